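#' Per-pixel camera calibration
#'
#' Bundles the three per-pixel maps of the standard sCMOS noise model:
#' the baseline offset (ADU), the gain (ADU per photo-electron) and the
#' read-noise variance (photo-electrons squared). Scalars are broadcast to
#' full maps so cameras calibrated with a single global gain are supported
#' alongside per-pixel calibrations.
#'
#' @param offset Offset map (ADU); matrix or scalar.
#' @param gain Gain map (ADU/e-); matrix or scalar, strictly positive.
#' @param readvar Read-noise variance map (e-^2); matrix or scalar,
#'   non-negative.
#' @param shape Integer vector `c(rows, cols)`; required when all three
#'   maps are scalars, otherwise inferred.
#'
#' @return A `camera_calibration` object.
#' @examples
#' cal <- camera_calibration(offset = 100, gain = 2, readvar = 1.6,
#'                           shape = c(32, 32))
#' @export
camera_calibration <- function(offset, gain, readvar, shape = NULL) {
  maps <- list(offset = offset, gain = gain, readvar = readvar)
  mat <- vapply(maps, is.matrix, logical(1))
  if (any(mat)) {
    dims <- lapply(maps[mat], dim)
    if (length(unique(dims)) != 1L) {
      stop("calibration maps must share a common shape", call. = FALSE)
    }
    shape <- dims[[1L]]
  } else if (is.null(shape)) {
    stop("`shape` is required when all maps are scalar", call. = FALSE)
  }
  shape <- as.integer(shape)
  maps <- lapply(maps, function(m) {
    if (is.matrix(m)) m else matrix(as.numeric(m), shape[1], shape[2])
  })
  if (any(!is.finite(maps$gain)) || any(maps$gain <= 0)) {
    stop("gain map must be strictly positive and finite", call. = FALSE)
  }
  if (any(!is.finite(maps$readvar)) || any(maps$readvar < 0)) {
    stop("read-noise variance map must be non-negative", call. = FALSE)
  }
  structure(
    list(offset = maps$offset, gain = maps$gain, readvar = maps$readvar,
         shape = shape),
    class = "camera_calibration"
  )
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf(
    "<camera_calibration> %d x %d px | median gain %.3g ADU/e- | median read noise %.3g e-\n",
    x$shape[1], x$shape[2], stats::median(x$gain),
    stats::median(sqrt(x$readvar))
  ))
  invisible(x)
}

#' Frame stack container
#'
#' A movie from one camera: pixel data as a 3D array indexed
#' `[row, col, frame]`, a units flag (`"adu"` for raw counts,
#' `"electrons"` after calibration) and a camera identifier.
#'
#' @param pixels 3D numeric array `[row, col, frame]`, or a matrix
#'   (single frame).
#' @param units `"adu"` or `"electrons"`.
#' @param camera_id Camera label.
#'
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(pixels, units = c("adu", "electrons"),
                        camera_id = "cam0") {
  units <- match.arg(units)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L) {
    stop("`pixels` must be a [row, col, frame] array", call. = FALSE)
  }
  if (units == "adu") {
    if (any(pixels < 0) || any(pixels != round(pixels))) {
      stop("raw ADU frames must contain non-negative integers", call. = FALSE)
    }
  } else if (any(!is.finite(pixels))) {
    stop("corrected frames must be finite", call. = FALSE)
  }
  structure(list(pixels = pixels, units = units, camera_id = camera_id),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_stack> %s | %d frames of %d x %d px [%s]\n",
              x$camera_id, d[3], d[1], d[2], x$units))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$pixels)

n_frames <- function(stack) dim(stack$pixels)[3]

#' Convert raw frames from ADU to photo-electrons
#'
#' Applies the per-pixel correction `(raw - offset) / gain` of the sCMOS
#' analysis model. Output values may be negative (read noise can undershoot
#' the offset); they are deliberately not clipped, since clipping would
#' bias downstream maximum-likelihood fits.
#'
#' @param raw A `frame_stack` in ADU.
#' @param cal A [camera_calibration()] matching the frame shape.
#'
#' @return A `frame_stack` in photo-electrons.
#' @examples
#' cal <- camera_calibration(100, 2, 1, shape = c(4, 4))
#' raw <- frame_stack(array(300L, c(4, 4, 1)))
#' correct_frames(raw, cal)$pixels[1, 1, 1]  # 100 e-
#' @export
correct_frames <- function(raw, cal) {
  stopifnot(inherits(raw, "frame_stack"), inherits(cal, "camera_calibration"))
  if (raw$units != "adu") {
    stop("frames are already in photo-electrons", call. = FALSE)
  }
  d <- dim(raw$pixels)
  if (!identical(d[1:2], cal$shape)) {
    stop(sprintf("frame shape %d x %d does not match calibration %d x %d",
                 d[1], d[2], cal$shape[1], cal$shape[2]), call. = FALSE)
  }
  corrected <- (raw$pixels - c(cal$offset)) / c(cal$gain)
  frame_stack(corrected, units = "electrons", camera_id = raw$camera_id)
}
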