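# Shared fixtures, built in code at test time.

# Default study-condition camera: gain 2 ADU/e-, offset 100 ADU,
# read noise 1.6 e- (variance 2.56 e-^2).
test_cal <- function(shape = c(32, 32), offset = 100, gain = 2,
                     readvar = 2.56) {
  camera_calibration(offset, gain, readvar, shape = shape)
}

# Analytic Gaussian-defocus PSF (130 nm in-focus width, 400 nm defocus
# depth) used as ground truth throughout.
test_psf3d <- function() gaussian_psf(130, depth = 400)

# Noiseless spline PSF built from the analytic model: 25 px laterally,
# 50 nm z steps over +/-900 nm.
analytic_spline <- function(psf = test_psf3d(), zmax = 900, dz = 50,
                            size = 25) {
  zs <- seq(-zmax, zmax, by = dz)
  ctr <- (size - 1) / 2
  stack <- array(0, c(size, size, length(zs)))
  for (i in seq_along(zs)) {
    stack[, , i] <- gauss_patch(psf, ctr, ctr, zs[i],
                                seq_len(size) - 1, seq_len(size) - 1,
                                108)$value
  }
  fit_spline(stack, zs)
}

# Localization table of jittering beads with optional per-bead missing
# frames (frame 0 always present).
make_bead_table <- function(seeds, n_frames, jitter = 0.1, seed = 1,
                            drop = NULL) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i) {
    fr <- 0:(n_frames - 1)
    if (!is.null(drop)) fr <- setdiff(fr, drop[[i]])
    data.frame(x = seeds$x[i] + rnorm(length(fr), 0, jitter),
               y = seeds$y[i] + rnorm(length(fr), 0, jitter),
               frame = fr, photons = 1000, background = 10,
               status = "converged")
  }))
  localization_table(rows[order(rows$frame), ], pixel_size = 108,
                     n_frames = n_frames)
}

# Simulate n isolated Gaussian spot windows (Poisson only) and fit them;
# returns fitted theta, status, and the true sub-pixel positions.
simulate_and_fit_spots <- function(n, N = 1000, b = 10, sigma = 130,
                                   a = 108, w = 15, seed = 1,
                                   readvar = 0) {
  psf <- gaussian_psf(sigma)
  ctr <- (w - 1) / 2
  withr_seed <- function(code) mvsmlm:::with_seed(seed, code)
  withr_seed({
    xs <- ctr + stats::runif(n) - 0.5
    ys <- ctr + stats::runif(n) - 0.5
    data <- matrix(0, n, w * w)
    rv <- matrix(readvar, n, w * w)
    init <- matrix(0, n, 5)
    for (k in seq_len(n)) {
      mu <- b + N * gauss_patch(psf, xs[k], ys[k], 0, seq_len(w) - 1,
                                seq_len(w) - 1, a)$value
      noisy <- stats::rpois(w * w, mu)
      if (readvar > 0) noisy <- noisy + stats::rnorm(w * w,
                                                     sd = sqrt(readvar))
      data[k, ] <- pmax(noisy, 0)
      init[k, ] <- c(ctr, ctr, N, b, sigma / a)
    }
    fit <- gauss_mle_batch(data, rv, init)
    list(theta = fit$theta, status = fit$status, x_true = xs, y_true = ys)
  })
}
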