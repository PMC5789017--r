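test_that("bead tracking follows the 2-pixel first-frame seed rule", {
  tab <- make_bead_table(data.frame(x = c(10, 40), y = c(10, 40)), 100)
  tr <- track_beads(tab, radius = 2)
  expect_equal(length(unique(na.omit(tr$track))), 2)
  expect_true(all(!is.na(tr$track)))
  expect_equal(max(table(tr$track)), 100)

  # a localization 2.5 px from the only seed stays unassigned
  tab2 <- localization_table(
    tibble::tibble(x = c(10, 12.5), y = c(10, 10), frame = c(0L, 1L),
                   photons = 1, background = 0),
    pixel_size = 108, n_frames = 2)
  tr2 <- track_beads(tab2, radius = 2)
  expect_true(is.na(tr2$track[2]))
})

test_that("tracking matches a brute-force nearest-seed oracle", {
  set.seed(179)
  seeds <- data.frame(x = runif(20, 5, 95), y = runif(20, 5, 95))
  tab <- make_bead_table(seeds, 40, jitter = 0.3, seed = 181)
  tr <- track_beads(tab, radius = 2)
  d2 <- outer(tab$x, seeds$x, `-`)^2 + outer(tab$y, seeds$y, `-`)^2
  oracle <- apply(d2, 1, which.min)
  oracle[sqrt(d2[cbind(seq_len(nrow(tab)), oracle)]) > 2] <- NA
  expect_equal(tr$track, as.integer(oracle))
})

test_that("track filtering enforces the strict >10% missing rule", {
  seeds <- data.frame(x = c(10, 40, 70), y = c(10, 40, 70))
  tab <- make_bead_table(seeds, 100, seed = 191,
                         drop = list(1:11, 1:10, integer(0)))
  tr <- track_beads(tab, radius = 2)
  kept <- filter_tracks(tr, movie_length = 100, max_missing = 0.10)
  ids <- sort(unique(kept$track))
  expect_equal(ids, c(2L, 3L))   # 11 missing discarded, 10 missing kept

  # paired mode: must pass on both cameras
  tab_b <- make_bead_table(seeds, 100, seed = 193,
                           drop = list(integer(0), 1:15, integer(0)))
  tr_b <- track_beads(tab_b, radius = 2)
  both <- filter_tracks(tr, movie_length = 100, paired = tr_b)
  expect_equal(sort(unique(both$track)), 3L)
})

test_that("precision statistics recover injected jitter and means", {
  seeds <- data.frame(x = 20, y = 30)
  jit_px <- 2 / 108    # 2 nm jitter
  tab <- make_bead_table(seeds, 100, jitter = jit_px, seed = 197)
  st <- precision_stats(track_beads(tab, radius = 2))
  expect_equal(nrow(st), 1)
  expect_lt(abs(st$std_x - 2) / 2, 0.3)
  expect_equal(st$mean_photons, 1000)
  expect_false(st$insufficient)

  const <- localization_table(
    tibble::tibble(x = rep(5, 20), y = rep(5, 20), frame = 0:19,
                   photons = 1, background = 0),
    pixel_size = 108, n_frames = 20)
  st0 <- precision_stats(track_beads(const, radius = 2))
  expect_equal(st0$std_x, 0)
  short <- localization_table(
    tibble::tibble(x = rep(5, 3), y = rep(5, 3), frame = 0:2,
                   photons = 1, background = 0),
    pixel_size = 108, n_frames = 3)
  expect_true(precision_stats(track_beads(short, radius = 2))$insufficient)
})

structure_table <- function(n, n_frames, drift_nm_x = 0, seed = 199) {
  set.seed(seed)
  ang <- runif(n, 0, 2 * pi)
  fr <- sample(0:(n_frames - 1), n, replace = TRUE)
  x <- 50 + 8 * cos(ang) + rnorm(n, 0, 0.1) +
    (drift_nm_x / 108) * fr / n_frames
  y <- 50 + 3 * sin(ang) + rnorm(n, 0, 0.1)
  localization_table(
    tibble::tibble(x = x, y = y, frame = fr, photons = 1000,
                   background = 10, status = "converged"),
    pixel_size = 108, n_frames = n_frames)
}

test_that("drift correction recovers injected linear drift", {
  tab <- structure_table(6000, 6000, drift_nm_x = 50)
  res <- drift_correct(tab, segment_frames = 1000, bin_size_nm = 20)
  truth <- 50 * res$drift$frame_mid / 6000
  truth <- truth - truth[1]
  expect_lt(sqrt(mean((res$drift$dx - truth)^2)), 10)
  expect_equal(res$drift$dx[1], 0)
  expect_equal(res$drift$dy[1], 0)
})

test_that("null drift stays below half a bin and is translation invariant", {
  tab <- structure_table(6000, 6000)
  res <- drift_correct(tab, segment_frames = 1000, bin_size_nm = 20)
  expect_lt(max(abs(c(res$drift$dx, res$drift$dy))), 10)

  shifted <- tab
  shifted$x <- shifted$x + 7.5
  shifted$y <- shifted$y - 3.25
  shifted <- localization_table(shifted, pixel_size = 108, n_frames = 6000)
  res2 <- drift_correct(shifted, segment_frames = 1000, bin_size_nm = 20)
  expect_equal(res2$drift$dx, res$drift$dx, tolerance = 1e-6)
  expect_equal(res2$drift$dy, res$drift$dy, tolerance = 1e-6)
})

test_that("z rescaling is the documented linear map", {
  tab <- localization_table(
    tibble::tibble(x = 1:3, y = 1:3, z = c(1000, 0, -400),
                   frame = 0:2, photons = 1, background = 0),
    pixel_size = 108, n_frames = 3)
  out <- rescale_z(tab)
  expect_equal(out$z, c(790, 0, -316))
  # two rescales compose multiplicatively
  twice <- rescale_z(rescale_z(tab, 0.9), 0.5)
  once <- rescale_z(tab, 0.45)
  expect_equal(twice$z, once$z)
  expect_equal(attr(twice, "z_rescale"), 0.45)
  # ordering and relative spacing preserved
  expect_equal(order(out$z), order(tab$z))
})

test_that("rendering conserves counts and resolves by bin size", {
  tab <- localization_table(
    tibble::tibble(x = c(10, 10 + 40 / 108), y = c(10, 10),
                   frame = c(0L, 0L), photons = 1, background = 0),
    pixel_size = 108, n_frames = 1)
  one <- render(tab[1, ], bin_size_nm = 10)
  expect_equal(sum(one != 0), 1)
  img_fine <- render(tab, bin_size_nm = 10)
  img_coarse <- render(tab, bin_size_nm = 50)
  expect_equal(sum(img_fine), 2)
  expect_equal(sum(img_coarse), 2)
  expect_equal(sum(img_fine != 0), 2)    # 40 nm apart: resolved at 10 nm
  expect_equal(sum(img_coarse != 0), 1)  # merged at 50 nm
  empty <- render(tab[0, ], bin_size_nm = 10)
  expect_equal(length(empty), 0)
  expect_equal(attr(empty, "bin_size_nm"), 10)
})
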