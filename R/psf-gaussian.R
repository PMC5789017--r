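#' Analytic Gaussian PSF model
#'
#' A 2D Gaussian PSF with optional first-order defocus: the width grows
#' with axial position as `sigma(z) = sigma0 * sqrt(1 + ((z - z0)/depth)^2)`,
#' the usual Gaussian-beam approximation for a high-NA widefield PSF near
#' focus. With `depth = NULL` the model is purely 2D (no z dependence).
#'
#' @param sigma0 In-focus width (nm), > 0.
#' @param depth Defocus depth parameter (nm); `NULL` for a 2D model.
#' @param z0 Focal position (nm).
#'
#' @return A `gaussian_psf` object.
#' @examples
#' psf2d <- gaussian_psf(130)
#' psf3d <- gaussian_psf(130, depth = 400)
#' @export
gaussian_psf <- function(sigma0, depth = NULL, z0 = 0) {
  stopifnot(sigma0 > 0, is.null(depth) || depth > 0)
  structure(list(sigma0 = sigma0, depth = depth, z0 = z0),
            class = c("gaussian_psf", "psf_model"))
}

#' @export
print.gaussian_psf <- function(x, ...) {
  cat(sprintf("<gaussian_psf> sigma0 = %g nm%s\n", x$sigma0,
              if (is.null(x$depth)) " (2D)"
              else sprintf(", defocus depth = %g nm", x$depth)))
  invisible(x)
}

# Width (nm) at axial position z (nm), and its derivative wrt z.
gauss_sigma_z <- function(psf, z) {
  if (is.null(psf$depth)) {
    list(sigma = rep(psf$sigma0, length(z)), dsigma_dz = rep(0, length(z)))
  } else {
    u <- (z - psf$z0) / psf$depth
    s <- psf$sigma0 * sqrt(1 + u^2)
    list(sigma = s, dsigma_dz = psf$sigma0^2 * (z - psf$z0) / (psf$depth^2 * s))
  }
}

# Pixel-integrated Gaussian PSF patch and its analytic derivatives.
# rows/cols: integer pixel coordinates (0-based convention allowed; only
# differences to (x, y) matter). Returns per-pixel photon fractions.
gauss_patch <- function(psf, x, y, z, rows, cols, pixel_size,
                        derivatives = FALSE) {
  sz <- gauss_sigma_z(psf, z)
  s_px <- sz$sigma / pixel_size
  ex <- pixel_gauss(cols, x, s_px)
  ey <- pixel_gauss(rows, y, s_px)
  val <- outer(ey, ex)
  if (!derivatives) {
    return(list(value = val))
  }
  dnorm_edge <- function(coords, center) {
    hi <- stats::dnorm((coords + 0.5 - center) / s_px)
    lo <- stats::dnorm((coords - 0.5 - center) / s_px)
    list(hi = hi, lo = lo,
         uhi = (coords + 0.5 - center) / s_px,
         ulo = (coords - 0.5 - center) / s_px)
  }
  gx <- dnorm_edge(cols, x)
  gy <- dnorm_edge(rows, y)
  dex_dx <- -(gx$hi - gx$lo) / s_px
  dey_dy <- -(gy$hi - gy$lo) / s_px
  # d/d sigma_px of the pixel integral
  dex_ds <- -(gx$hi * gx$uhi - gx$lo * gx$ulo) / s_px
  dey_ds <- -(gy$hi * gy$uhi - gy$lo * gy$ulo) / s_px
  dval_ds_px <- outer(dey_ds, ex) + outer(ey, dex_ds)
  list(
    value = val,
    dx = outer(ey, dex_dx),
    dy = outer(dey_dy, ex),
    dz = dval_ds_px * (sz$dsigma_dz / pixel_size),
    dsigma_px = dval_ds_px
  )
}

#' Evaluate a PSF model on a pixel grid
#'
#' Returns the expected fraction of a single emitter's photons falling in
#' each pixel of an odd-sized window centred on the emitter's nearest
#' pixel. Fractions sum to at most 1 (light outside the window is lost to
#' the model).
#'
#' @param psf A `gaussian_psf` or `spline_psf`.
#' @param x,y Emitter position (pixels, 0-based; x along columns).
#' @param z Axial position (nm). Ignored by 2D models.
#' @param window Odd window size (pixels).
#' @param pixel_size Pixel size (nm).
#'
#' @return A `window x window` matrix of photon fractions.
#' @examples
#' p <- evaluate_psf(gaussian_psf(130), x = 7, y = 7, z = 0,
#'                   window = 15, pixel_size = 108)
#' sum(p)  # > 0.999
#' @export
evaluate_psf <- function(psf, x, y, z = 0, window = 15, pixel_size = 108) {
  stopifnot(window >= 3, is_odd(window))
  half <- (window - 1L) / 2L
  rows <- round(y) + seq(-half, half)
  cols <- round(x) + seq(-half, half)
  psf_patch(psf, x, y, z, rows, cols, pixel_size)$value
}

# Internal dispatch shared by the fitter, the simulator and the CRB code.
psf_patch <- function(psf, x, y, z, rows, cols, pixel_size,
                      derivatives = FALSE) {
  UseMethod("psf_patch")
}

#' @export
psf_patch.gaussian_psf <- function(psf, x, y, z, rows, cols, pixel_size,
                                   derivatives = FALSE) {
  gauss_patch(psf, x, y, z, rows, cols, pixel_size, derivatives)
}
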