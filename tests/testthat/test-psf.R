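test_that("pixel-integrated Gaussian PSF is normalized and symmetric", {
  patch <- evaluate_psf(gaussian_psf(130), x = 7, y = 7, z = 0,
                        window = 15, pixel_size = 108)
  expect_gt(sum(patch), 0.999)
  expect_lte(sum(patch), 1)
  expect_equal(patch, t(patch), tolerance = 1e-12)           # 90 deg rotation
  expect_equal(patch, patch[15:1, ], tolerance = 1e-12)      # mirror

  # translation equivariance: shifting the emitter by one pixel shifts
  # the patch by one pixel
  p0 <- gauss_patch(gaussian_psf(130), 7, 7, 0, 0:14, 0:14, 108)$value
  p1 <- gauss_patch(gaussian_psf(130), 8, 7, 0, 0:14, 1:15, 108)$value
  expect_equal(p0, p1, tolerance = 1e-14)
})

test_that("spline PSF interpolates its input stack exactly", {
  sp <- analytic_spline(zmax = 400, size = 15)
  zs <- sp$z_values
  for (i in c(1, 4, 9)) {
    got <- psf_patch(sp, 7, 7, zs[i], 0:14, 0:14, 108)$value
    expect_equal(got, sp$stack[, , i], tolerance = 1e-8)
  }
})

test_that("spline PSF matches the analytic model between knots", {
  psf <- test_psf3d()
  sp <- analytic_spline(psf)
  for (z in c(-433, 123, 617)) {
    got <- psf_patch(sp, 12.3, 11.6, z, 3:21, 3:21, 108)$value
    want <- gauss_patch(psf, 12.3, 11.6, z, 3:21, 3:21, 108)$value /
      sp$normalization
    expect_lt(max(abs(got - want)) / max(want), 0.01)
  }
})

test_that("spline z-derivative vanishes at a symmetric focus", {
  sp <- analytic_spline()   # symmetric about z = 0
  d <- psf_patch(sp, 12, 12, 0, 0:24, 0:24, 108, derivatives = TRUE)
  expect_lt(max(abs(d$dz)), 1e-6 * max(d$value))
  # and analytic derivatives agree with finite differences off-focus
  d2 <- psf_patch(sp, 11.7, 12.4, 217, 5:19, 5:19, 108, derivatives = TRUE)
  fd <- (psf_patch(sp, 11.7, 12.4, 218, 5:19, 5:19, 108)$value -
           psf_patch(sp, 11.7, 12.4, 216, 5:19, 5:19, 108)$value) / 2
  expect_equal(d2$dz, fd, tolerance = 1e-4)
})

test_that("spline evaluation outside the z range is a range error", {
  sp <- analytic_spline(zmax = 400)
  expect_error(psf_patch(sp, 12, 12, 500, 0:24, 0:24, 108), "range")
  expect_error(fit_spline(array(c(NA, rep(1, 26)), c(3, 3, 3)),
                          c(0, 50, 100)), "non-finite")
})

test_that("crowded beads are rejected and an isolated bead averages to itself", {
  # two beads 10 px apart: both rejected, calibration error raised
  slices <- array(1, c(40, 40, 3))
  expect_error(
    average_bead_stack(list(slices),
                       data.frame(x = c(15, 25), y = c(20, 20))),
    "no beads survive")
  expect_error(
    average_bead_stack(list(slices), data.frame(x = 20, y = 20),
                       visible = matrix(FALSE, 1, 1)),
    "no beads survive")

  # one isolated noiseless bead: the average is that bead's aligned stack
  psf <- test_psf3d()
  zs <- seq(-200, 200, by = 100)
  arr <- array(0, c(41, 41, length(zs)))
  for (i in seq_along(zs)) {
    arr[, , i] <- 30000 * gauss_patch(psf, 20.3, 19.8, zs[i], 0:40, 0:40,
                                      108)$value + 5
  }
  avg <- average_bead_stack(list(arr), data.frame(x = 20.3, y = 19.8),
                            roi_size = 15)[[1]]
  ctr <- 7
  want <- gauss_patch(psf, ctr, ctr, 0, 0:14, 0:14, 108)$value
  expect_equal(avg[, , which(zs == 0)] / sum(avg[, , which(zs == 0)]),
               want / sum(want), tolerance = 0.01)
})

test_that("averaging many noisy beads converges to the noiseless PSF", {
  psf <- test_psf3d()
  cal <- camera_calibration(100, 2, 2.56, shape = c(200, 200))
  set.seed(57)
  gx <- rep(seq(30, 170, by = 35), times = 5)
  gy <- rep(seq(30, 170, by = 35), each = 5)
  beads <- data.frame(x = gx + runif(25, -2, 2), y = gy + runif(25, -2, 2))
  zst <- simulate_bead_zstack(beads, psf, plane_geometry(0, 1), cal,
                              z_range = c(-200, 200), z_step = 100,
                              frames_per_z = 1, seed = 59,
                              background = 5, photons = 20000)
  slices <- collapse_zstack(correct_frames(zst$stacks[[1]], cal), 1)
  avg <- average_bead_stack(list(slices), beads, roi_size = 15)[[1]]
  mid <- (dim(avg)[3] + 1) / 2
  want <- gauss_patch(psf, 7, 7, 0, 0:14, 0:14, 108)$value
  got <- avg[, , mid] / sum(avg[, , mid])
  want <- want / sum(want)
  expect_lt(max(abs(got - want)) / max(want), 0.02)
})
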