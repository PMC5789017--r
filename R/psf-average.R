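#' Average bead z-stacks into a PSF stack
#'
#' Builds the averaged PSF stack that [fit_spline()] consumes. Beads closer
#' than `exclusion_radius` to any neighbour are discarded (their images
#' overlap), as are beads not visible on every plane when `require_common`
#' is set. Each surviving bead is background-subtracted (median of the ROI
#' border ring per slice), sub-pixel aligned by Gaussian-fitting its
#' sharpest slice, normalized to unit in-focus signal, and averaged.
#'
#' @param stacks List of bead z-stacks, one per plane: `frame_stack`
#'   objects (frames ordered by increasing stage z) or `[y, x, z]` arrays.
#' @param beads Data frame with columns `x`, `y`: bead positions in the
#'   reference camera frame (0-based pixels).
#' @param exclusion_radius Minimum allowed distance to the nearest
#'   neighbouring bead (pixels).
#' @param require_common Discard beads not visible on every plane.
#' @param visible Optional logical matrix `[bead, plane]` of per-plane
#'   visibility; defaults to all visible.
#' @param transforms Optional list of [affine2d()] transforms
#'   (secondary -> reference), one per plane; plane 1 may be `NULL`
#'   (identity). Bead positions are mapped into each plane's own frame
#'   before extraction.
#' @param roi_size Odd ROI size (pixels) for the extracted sub-images.
#' @param psf_sigma_px Rough PSF width (pixels) used by the alignment fit.
#'
#' @return List of averaged stacks (arrays `[y, x, z]`), one per plane.
#' @export
average_bead_stack <- function(stacks, beads, exclusion_radius = 24,
                               require_common = TRUE, visible = NULL,
                               transforms = NULL, roi_size = 15,
                               psf_sigma_px = 1.3) {
  stopifnot(is_odd(roi_size), roi_size >= 7)
  arrays <- lapply(stacks, function(s) {
    if (inherits(s, "frame_stack")) s$pixels else s
  })
  n_planes <- length(arrays)
  nb <- nrow(beads)
  if (is.null(visible)) visible <- matrix(TRUE, nb, n_planes)

  reasons <- character(0)
  keep <- rep(TRUE, nb)
  if (nb > 1L) {
    dmat <- as.matrix(stats::dist(cbind(beads$x, beads$y)))
    diag(dmat) <- Inf
    crowded <- apply(dmat, 1, min) < exclusion_radius
    if (any(crowded)) {
      reasons <- c(reasons, sprintf(
        "%d bead(s) within %g px of a neighbour", sum(crowded),
        exclusion_radius))
      keep <- keep & !crowded
    }
  }
  if (require_common) {
    missing <- !apply(visible, 1, all)
    if (any(missing & keep)) {
      reasons <- c(reasons, sprintf(
        "%d bead(s) not visible on all planes", sum(missing & keep)))
    }
    keep <- keep & !missing
  }
  if (!any(keep)) {
    stop(paste0("calibration error: no beads survive selection (",
                paste(reasons, collapse = "; "), ")"), call. = FALSE)
  }

  half <- (roi_size - 1L) / 2L
  lapply(seq_len(n_planes), function(p) {
    arr <- arrays[[p]]
    nz <- dim(arr)[3]
    tr <- if (!is.null(transforms)) transforms[[p]] else NULL
    acc <- array(0, c(roi_size, roi_size, nz))
    n_used <- 0L
    for (b in which(keep)) {
      pos <- c(beads$x[b], beads$y[b])
      if (!is.null(tr)) pos <- drop(apply_affine(invert_affine(tr), pos))
      ic <- round(pos)
      rows <- (ic[2] - half):(ic[2] + half) + 1L   # 1-based array rows
      cols <- (ic[1] - half):(ic[1] + half) + 1L
      if (min(rows, cols) < 1L || max(rows) > dim(arr)[1] ||
          max(cols) > dim(arr)[2]) {
        next
      }
      roi <- arr[rows, cols, , drop = FALSE]
      # per-slice background: median of the ROI border ring
      border <- c(1L, roi_size)
      for (s in seq_len(nz)) {
        ring <- c(roi[border, , s], roi[-border, border, s])
        roi[, , s] <- roi[, , s] - stats::median(ring)
      }
      # sharpest slice -> sub-pixel centre via Gaussian MLE
      focus <- which.max(apply(roi, 3, max))
      fit <- fit_gauss_window(roi[, , focus], sigma_px = psf_sigma_px)
      # resample so the bead centre lands on the ROI centre pixel
      dyx <- c(fit$y - half, fit$x - half)   # 0-based offsets within ROI
      aligned <- array(0, dim(roi))
      grid0 <- seq_len(roi_size) - 1
      for (s in seq_len(nz)) {
        aligned[, , s] <- bspline_shift(roi[, , s],
                                        grid0 + dyx[1], grid0 + dyx[2])
      }
      tot <- sum(aligned[, , focus])
      if (!is.finite(tot) || tot <= 0) next
      acc <- acc + aligned / tot
      n_used <- n_used + 1L
    }
    if (n_used == 0L) {
      stop("calibration error: no bead ROI could be extracted on plane ",
           p, call. = FALSE)
    }
    acc / n_used
  })
}

# Resample `mat` at fractional 0-based grid coordinates with an
# interpolating cubic B-spline (sharper than bilinear: the bead core is
# narrow and linear resampling would visibly flatten the averaged peak).
# Coordinates outside the grid evaluate to 0.
bspline_shift <- function(mat, rows0, cols0) {
  cr <- bspline_prefilter(mat)                       # rows
  cc <- t(bspline_prefilter(t(cr)))                  # then columns
  Wr <- bspline_weights(rows0, nrow(mat))
  Wc <- bspline_weights(cols0, ncol(mat))
  Wr %*% cc %*% t(Wc)
}

# Bilinear interpolation of `mat` at (possibly fractional) 1-based row/col
# coordinate matrices; out-of-range coordinates are edge-clamped.
bilinear_sample <- function(mat, rr, cc) {
  nr <- nrow(mat); nc <- ncol(mat)
  rr <- pmin(pmax(rr, 1), nr)
  cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rr), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- rr - r0; fc <- cc - c0
  v00 <- mat[cbind(c(r0), c(c0))]
  v10 <- mat[cbind(c(r0 + 1), c(c0))]
  v01 <- mat[cbind(c(r0), c(c0 + 1))]
  v11 <- mat[cbind(c(r0 + 1), c(c0 + 1))]
  out <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  matrix(out, nrow(rr), ncol(rr))
}
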