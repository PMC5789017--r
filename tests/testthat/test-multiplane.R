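biplane_fixture <- function(n_frames, seed, z = 0, N = 3640, b = 30,
                            shape = c(24, 24)) {
  psf <- test_psf3d()
  geom <- biplane_geometry(600)
  cal <- test_cal(shape = shape)
  sp <- analytic_spline(psf)
  em <- emitters(x = 11.5, y = 11.3, z = z, photons = N,
                 on_frames = list(seq_len(n_frames) - 1L))
  mov <- simulate_movie(em, psf, geom, cal, background = b,
                        n_frames = n_frames, seed = seed)
  stacks <- lapply(mov, correct_frames, cal = cal)
  list(stacks = stacks, cal = cal, sp = sp, geom = geom, em = em)
}

test_that("an emitter midway between biplane foci splits its signal 50/50", {
  psf <- test_psf3d()
  geom <- biplane_geometry(600)
  cal <- camera_calibration(100, 2, 0, shape = c(24, 24))
  sp <- analytic_spline(psf)
  # noiseless expected images via the internal renderer
  em <- emitters(x = 11.5, y = 11.3, z = 0, photons = 4000,
                 on_frames = list(0L))
  stacks <- lapply(1:2, function(p) {
    mu <- mvsmlm:::expected_plane_image(em, psf, geom, p, c(24, 24), 20, 108)
    frame_stack(mu, units = "electrons")
  })
  fit <- fit_multiplane(stacks, cal, sp, geom,
                        fit_config(threshold = 8),
                        candidates = tibble::tibble(x = 11.5, y = 11.3,
                                                    frame = 0L))
  expect_equal(fit$status, "converged")
  expect_lt(abs(fit$signal_1 - fit$signal_2) / fit$photons, 0.01)
  expect_equal(fit$signal_1 + fit$signal_2, fit$photons,
               tolerance = 0.02)
  expect_lt(abs(fit$z), 5)
  expect_lt(abs(fit$x - 11.5), 0.01)
})

test_that("biplane fitting recovers z across the inter-plane range", {
  for (z in c(-200, 150)) {
    fx <- biplane_fixture(25, seed = 113 + z, z = z)
    locs <- fit_multiplane(fx$stacks, fx$cal, fx$sp, fx$geom,
                           fit_config(threshold = 8))
    ok <- locs$status == "converged"
    expect_gt(sum(ok), 20)
    expect_lt(abs(median(locs$z[ok]) - z), 15)
  }
})

test_that("a dead plane yields near-zero measured signal but the fit converges", {
  psf <- test_psf3d()
  geom <- quadplane_geometry(500)
  cal <- test_cal(shape = c(24, 24))
  sp <- analytic_spline(psf, zmax = 1300)
  em <- emitters(x = 11.5, y = 11.3, z = 0, photons = 8000,
                 on_frames = list(0:9))
  mov <- simulate_movie(em, psf, geom, cal, background = 20,
                        n_frames = 10, seed = 127)
  stacks <- lapply(mov, correct_frames, cal = cal)
  # replace the most defocused plane with pure background
  dead <- simulate_movie(emitters(numeric(0), numeric(0),
                                  photons = numeric(0),
                                  on_frames = list())[0, ],
                         psf, plane_geometry(0, 1), cal,
                         background = 20, n_frames = 10, seed = 131)
  stacks[[4]] <- correct_frames(dead[[1]], cal)
  locs <- fit_multiplane(stacks, cal, sp, geom, fit_config(threshold = 6))
  ok <- locs$status == "converged"
  expect_gt(sum(ok), 5)
  expect_lt(abs(mean(locs$signal_4[ok])), 0.15 * mean(locs$signal_1[ok]))
  expect_lt(abs(mean(locs$x[ok]) - 11.5), 0.1)
})

test_that("multiplane optimizer traces are non-decreasing", {
  fx <- biplane_fixture(3, seed = 137)
  locs <- fit_multiplane(fx$stacks, fx$cal, fx$sp, fx$geom,
                         fit_config(threshold = 8), trace = TRUE)
  for (tr in attr(locs, "trace")) {
    expect_true(all(diff(tr) >= -1e-9))
  }
})

test_that("candidates from secondary planes are mapped through transforms", {
  psf <- test_psf3d()
  shift <- affine2d(diag(2), c(2.25, -1.5))   # plane2 -> reference
  geom <- plane_geometry(c(-300, 300), c(0.5, 0.5),
                         transforms = list(NULL, shift), id = "biplane")
  cal <- test_cal(shape = c(26, 26))
  sp <- analytic_spline(psf)
  em <- emitters(x = 12.5, y = 12.8, z = 50, photons = 6000,
                 on_frames = list(0:9))
  mov <- simulate_movie(em, psf, geom, cal, background = 20,
                        n_frames = 10, seed = 139)
  stacks <- lapply(mov, correct_frames, cal = cal)
  locs <- fit_multiplane(stacks, cal, sp, geom, fit_config(threshold = 8))
  ok <- locs$status == "converged"
  expect_gt(sum(ok), 8)
  expect_lt(abs(median(locs$x[ok]) - 12.5), 0.05)
  expect_lt(abs(median(locs$y[ok]) - 12.8), 0.05)
})
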