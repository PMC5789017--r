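#' Mortensen localization-precision bound (2D Gaussian MLE)
#'
#' The Cramer-Rao bound on the lateral precision of maximum-likelihood
#' Gaussian fitting with Poisson noise and uniform background, evaluated
#' by adaptive numerical quadrature. With `sigma_a^2 = sigma^2 + a^2/12`
#' (pixelation-corrected PSF width) and `tau = 2 pi sigma_a^2 b / (N a^2)`,
#' the bound is
#' `sigma_x^2 = (sigma_a^2 / N) / ( -integral_0^1 t ln(t) / (t + tau) dt )`,
#' which reduces to `sigma_a^2 / N` in the zero-background limit.
#'
#' @param N Total signal (photo-electrons), > 0.
#' @param b Background (photo-electrons per pixel), >= 0.
#' @param a Pixel size (nm), > 0.
#' @param sigma PSF Gaussian width (nm), > 0.
#'
#' @return A `crb_result` with `sigma_x = sigma_y` (nm).
#' @examples
#' mortensen_crb(N = 9100, b = 53, a = 108, sigma = 130)  # ~1.7 nm
#' @export
mortensen_crb <- function(N, b, a = 108, sigma = 130) {
  stopifnot(N > 0, b >= 0, a > 0, sigma > 0)
  sigma_a2 <- sigma^2 + a^2 / 12
  tau <- 2 * pi * sigma_a2 * b / (N * a^2)
  I <- stats::integrate(function(t) -t * log(t) / (t + tau), 0, 1,
                        rel.tol = 1e-8)
  if (I$message != "OK") {
    stop("numerical error in quadrature: ", I$message, call. = FALSE)
  }
  sx <- sqrt(sigma_a2 / N / I$value)
  crb_result(sigma_x = sx, sigma_y = sx, sigma_z = NA_real_,
             method = "mortensen")
}

crb_result <- function(sigma_x, sigma_y, sigma_z, method, window = NA) {
  structure(list(sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
                 method = method, window = window),
            class = "crb_result")
}

#' @export
print.crb_result <- function(x, ...) {
  cat(sprintf("<crb_result:%s> sigma_x = %.4g nm, sigma_y = %.4g nm%s\n",
              x$method, x$sigma_x, x$sigma_y,
              if (is.finite(x$sigma_z %||% NA)) {
                sprintf(", sigma_z = %.4g nm", x$sigma_z)
              } else {
                ""
              }))
  invisible(x)
}

#' Fisher-information CRB for arbitrary (multi)plane PSF models
#'
#' Builds the Fisher information matrix
#' `I_ij = sum_planes sum_pixels (dmu/dtheta_i)(dmu/dtheta_j) / (mu + readvar)`
#' for `theta = (x, y, z, N, b_1..b_P)` with `mu` the per-pixel expected
#' signal, and returns `sqrt(diag(I^-1))` for x, y and z. Sums run over a
#' finite window per plane; at the usual sigma/pixel ratios the excluded
#' contribution is negligible and the window used is recorded in the
#' result. For 2D PSF models (no defocus), z is dropped from `theta`.
#'
#' @param psf PSF model per plane (one model or a list per plane); spline
#'   PSF derivatives are taken analytically from the coefficients.
#' @param geometry A [plane_geometry()] (its transforms are ignored here;
#'   bounds are geometry-independent of registration).
#' @param N Total signal (e-).
#' @param b Background (e-/pixel/plane); scalar or per-plane.
#' @param readvar Read-noise variance (e-^2/pixel).
#' @param z Axial position (nm) at which to evaluate the bound.
#' @param pixel_size Pixel size (nm).
#' @param window Odd window size per plane (pixels).
#' @param x,y Sub-pixel emitter position within the window's central pixel.
#'
#' @return A `crb_result` with `sigma_x`, `sigma_y`, `sigma_z` (nm).
#' @examples
#' g <- plane_geometry(0, 1)
#' fisher_crb(gaussian_psf(130), g, N = 1000, b = 10, readvar = 0, z = 0)
#' @export
fisher_crb <- function(psf, geometry, N, b, readvar = 0, z = 0,
                       pixel_size = 108, window = 15, x = 0, y = 0) {
  P <- geometry$n_planes
  psfs <- if (inherits(psf, "psf_model")) rep(list(psf), P) else psf
  bg <- rep(b, length.out = P)
  half <- (window - 1L) / 2L
  coords <- seq(-half, half)
  has_z <- !(inherits(psfs[[1]], "gaussian_psf") && is.null(psfs[[1]]$depth))
  np <- 3L + has_z + P
  Imat <- matrix(0, np, np)
  for (p in seq_len(P)) {
    pa <- psf_patch(psfs[[p]], x, y, z - geometry$focal_offsets[p],
                    coords, coords, pixel_size, derivatives = TRUE)
    tpN <- geometry$transmissions[p] * N
    mu <- tpN * pa$value + bg[p]
    denom <- pmax(mu + readvar, 1e-12)
    D <- cbind(c(tpN * pa$dx / pixel_size),       # d mu / dx in nm
               c(tpN * pa$dy / pixel_size),
               if (has_z) c(tpN * pa$dz),
               c(geometry$transmissions[p] * pa$value))
    D <- cbind(D, matrix(0, nrow(D), P))
    D[, 3L + has_z + p] <- 1
    Imat <- Imat + crossprod(D, D / c(denom))
  }
  # Jacobi preconditioning keeps the inversion stable when parameters have
  # wildly different information content (e.g. background near zero)
  sc <- 1 / sqrt(pmax(diag(Imat), 1e-300))
  Iscaled <- Imat * outer(sc, sc)
  Iinv <- tryCatch(solve(Iscaled) * outer(sc, sc), error = function(e) {
    ev <- eigen(Iscaled, symmetric = TRUE)
    dir <- c("x", "y", if (has_z) "z", "N",
             paste0("b", seq_len(P)))[which.max(abs(
               ev$vectors[, which.min(ev$values)]))]
    stop("numerical error: singular Fisher matrix (uninformative direction: ",
         dir, ")", call. = FALSE)
  })
  v <- diag(Iinv)
  if (any(v[seq_len(2L + has_z)] <= 0)) {
    stop("numerical error: Fisher matrix not positive definite",
         call. = FALSE)
  }
  crb_result(sigma_x = sqrt(v[1]), sigma_y = sqrt(v[2]),
             sigma_z = if (has_z) sqrt(v[3]) else NA_real_,
             method = "fisher", window = window)
}

#' EMCCD excess-noise equivalence
#'
#' The multiplicative noise of an EMCCD's gain register degrades the
#' effective signal-to-noise as if the detected signal were halved; both
#' the signal and the background traverse the same register, so both are
#' halved before being handed to either CRB calculator.
#'
#' @param N Signal (e-), >= 0.
#' @param b Background (e-/pixel), >= 0.
#' @return List with halved `N` and `b`.
#' @examples
#' emccd_equivalent(1000, 20)  # N = 500, b = 10
#' @export
emccd_equivalent <- function(N, b = 0) {
  stopifnot(N >= 0, b >= 0)
  list(N = N / 2, b = b / 2)
}

#' Photon-cost multiplier between two plane geometries
#'
#' Finds the factor by which the photon budget of configuration
#' `geometry_b` must be multiplied for its lateral Fisher-CRB to match
#' that of `geometry_a` at axial position `z`, all else equal. Splitting
#' light over more planes dilutes the per-plane signal, so a quadplane
#' setup needs roughly twice the photons of a biplane setup at a z where
#' only its two nearest planes carry usable signal.
#'
#' @param psf PSF model (shared by both configurations).
#' @param geometry_a,geometry_b Reference and test [plane_geometry()]s.
#' @param N Photon budget of configuration a (e-).
#' @param b Background (e-/pixel/plane, same in both).
#' @param z Test axial position (nm).
#' @param readvar,pixel_size,window Passed to [fisher_crb()].
#' @param interval Search interval for the multiplier.
#'
#' @return The scalar multiplier.
#' @export
photon_cost_ratio <- function(psf, geometry_a, geometry_b, N, b, z = 0,
                              readvar = 0, pixel_size = 108, window = 15,
                              interval = c(0.5, 8)) {
  target <- fisher_crb(psf, geometry_a, N, b, readvar, z,
                       pixel_size, window)$sigma_x
  f <- function(m) {
    fisher_crb(psf, geometry_b, m * N, b, readvar, z,
               pixel_size, window)$sigma_x - target
  }
  stats::uniroot(f, interval, tol = 1e-6)$root
}
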