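test_that("background-only frames have the configured mean", {
  cal <- camera_calibration(100, 1, 0.81, shape = c(100, 100))
  mov <- simulate_movie(emitters(numeric(0), numeric(0),
                                 photons = numeric(0),
                                 on_frames = list())[0, ],
                        gaussian_psf(130), plane_geometry(0, 1), cal,
                        background = 10, n_frames = 1, seed = 2)
  px <- mov[[1]]$pixels
  sem <- sd(px) / sqrt(length(px))
  expect_lt(abs(mean(px) - 110), 5 * sem)
})

test_that("quadplane splitting delivers N/4 per plane and conserves photons", {
  cal <- test_cal(shape = c(31, 31))
  geom <- quadplane_geometry(500)
  psf <- test_psf3d()
  N <- 20000
  em <- emitters(x = 15, y = 15, z = 0, photons = N, on_frames = list(0:19))
  mov <- simulate_movie(em, psf, geom, cal, background = 2, n_frames = 20,
                        seed = 11)
  plane_sums <- vapply(mov, function(s) {
    corr <- correct_frames(s, cal)$pixels
    mean(apply(corr, 3, sum) - 2 * 31 * 31)
  }, numeric(1))
  # each plane's summed corrected spot signal ~ N/4 within Poisson error
  tol <- 3 * sqrt(N / 4) / sqrt(20) + 0.02 * N / 4   # MC + window truncation
  for (p in 1:4) expect_lt(abs(plane_sums[p] - N / 4), tol)
  # photon conservation across planes
  expect_lt(abs(sum(plane_sums) - N), 4 * tol)
})

test_that("single-emitter signal in a 15x15 box is conserved", {
  cal <- camera_calibration(100, 2, 0, shape = c(15, 15))
  em <- emitters(x = 7, y = 7, z = 0, photons = 5000,
                 on_frames = list(0L))
  mov <- simulate_movie(em, gaussian_psf(130), plane_geometry(0, 1), cal,
                        background = 10, n_frames = 1, seed = 3)
  corr <- correct_frames(mov[[1]], cal)
  got <- sum(corr$pixels) - 10 * 15 * 15
  expect_lt(abs(got - 5000), 3 * sqrt(5000 + 10 * 225))
})

test_that("identical seeds give bit-identical stacks, different seeds differ", {
  cal <- test_cal(shape = c(16, 16))
  em <- emitters(x = 8, y = 8, z = 0, photons = 2000, on_frames = list(0L))
  args <- list(em, test_psf3d(), biplane_geometry(), cal, 10, 1)
  m1 <- do.call(simulate_movie, c(args, seed = 17))
  m2 <- do.call(simulate_movie, c(args, seed = 17))
  m3 <- do.call(simulate_movie, c(args, seed = 18))
  expect_identical(m1[[1]]$pixels, m2[[1]]$pixels)
  expect_identical(m1[[2]]$pixels, m2[[2]]$pixels)
  expect_false(identical(m1[[1]]$pixels, m3[[1]]$pixels))
})

test_that("corrected background pixels show Poisson + read-noise variance", {
  cal <- camera_calibration(100, 2, 4, shape = c(320, 320))
  mov <- simulate_movie(emitters(numeric(0), numeric(0),
                                 photons = numeric(0),
                                 on_frames = list())[0, ],
                        gaussian_psf(130), plane_geometry(0, 1), cal,
                        background = 25, n_frames = 1, seed = 23)
  px <- correct_frames(mov[[1]], cal)$pixels
  n <- length(px)
  expected_var <- 25 + 4
  # sampling error of a variance over n iid samples
  tol <- 5 * expected_var * sqrt(2 / n)
  expect_lt(abs(stats::var(c(px)) - expected_var), tol + 0.15)
})

test_that("bead z-stacks are brightest at a plane's focus and bleach-free", {
  cal <- test_cal(shape = c(24, 24))
  geom <- biplane_geometry(600)    # planes at -300 and +300 nm
  beads <- data.frame(x = 11, y = 11)
  zst <- simulate_bead_zstack(beads, test_psf3d(), geom, cal,
                              z_range = c(-600, 600), z_step = 100,
                              frames_per_z = 1, seed = 29,
                              background = 2, photons = 50000)
  corr <- collapse_zstack(correct_frames(zst$stacks[[1]], cal), 1)
  peaks <- apply(corr, 3, max)
  expect_equal(zst$schedule$z[which.max(peaks)], -300)
  # constant brightness: total signal flat across z within noise
  tots <- apply(corr, 3, sum) - 2 * 24 * 24
  expect_lt(diff(range(tots)) / mean(tots), 0.1)
  expect_error(
    simulate_bead_zstack(beads, test_psf3d(), geom, cal,
                         z_range = c(-100, 100), z_step = 50,
                         frames_per_z = 1, seed = 1),
    "configuration error")
})

test_that("geometry validation catches bad transmissions and offsets", {
  expect_error(plane_geometry(c(0, 600), c(0.6, 0.6)), "sum to 1")
  expect_error(plane_geometry(c(600, 0), c(0.5, 0.5)), "increasing")
  expect_error(plane_geometry(c(0, 1, 2), rep(1 / 3, 3)), "planes")
})

test_that("emitters outside the frame warn and render clipped", {
  cal <- test_cal(shape = c(16, 16))
  em <- emitters(x = -5, y = 8, z = 0, photons = 1000,
                 on_frames = list(0L))
  expect_warning(
    simulate_movie(em, gaussian_psf(130), plane_geometry(0, 1), cal,
                   background = 5, n_frames = 1, seed = 251),
    "outside")
})

test_that("spectral simulation follows the multinomial-thinning model", {
  # degenerate signature: all signal in one channel
  one <- simulate_spectral_localizations(list(dye_signature(c(1, 0, 0, 0))),
                                         n_per_dye = 50, seed = 41)
  expect_true(all(one$signal_2 == 0 & one$signal_3 == 0 & one$signal_4 == 0))
  expect_true(all(one$signal_1 > 0))

  sig <- dye_signature(c(0.4, 0.3, 0.2, 0.1))
  sim <- simulate_spectral_localizations(list(sig), n_per_dye = 2000,
                                         mean_photons = 1000, seed = 43)
  fr <- colMeans(as.matrix(sim[, paste0("signal_", 1:4)]))
  expect_equal(unname(fr / sum(fr)), c(0.4, 0.3, 0.2, 0.1),
               tolerance = 0.02)
  expect_error(dye_signature(c(0.5, 0.6, -0.1, 0)), "non-negative")
})
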