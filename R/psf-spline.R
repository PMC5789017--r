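#' Cubic-spline PSF model from measured bead stacks
#'
#' The measured-PSF counterpart to [gaussian_psf()]: a 3D tensor-product
#' cubic B-spline interpolant of an averaged bead z-stack, evaluable (with
#' analytic first derivatives) at arbitrary sub-pixel/sub-slice positions.
#' The interpolant reproduces the input stack exactly at every grid point
#' and is C2-continuous between samples.
#'
#' @name spline_psf
NULL

# Interpolating cubic B-spline prefilter (natural end conditions).
# D: n x m matrix of data columns; returns the (n + 2) x m coefficient
# matrix c such that (c[i] + 4 c[i+1] + c[i+2]) / 6 = D[i, ].
bspline_prefilter <- function(D) {
  n <- nrow(D)
  A <- matrix(0, n + 2L, n + 2L)
  A[1L, 1:3] <- c(1, -2, 1)
  for (i in seq_len(n)) A[i + 1L, i:(i + 2L)] <- c(1, 4, 1) / 6
  A[n + 2L, n:(n + 2L)] <- c(1, -2, 1)
  solve(A, rbind(0, D, 0))
}

# Cubic B-spline basis and derivative at fractional positions t in [0, 1].
# Returns 4-column matrices (one row per t).
bspline_basis <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}
bspline_dbasis <- function(t) {
  cbind(-(1 - t)^2 / 2,
        (3 * t^2 - 4 * t) / 2,
        (-3 * t^2 + 2 * t + 1) / 2,
        t^2 / 2)
}

# Split grid coordinates into interval index (0-based) and fraction;
# coordinates outside [0, n-1] are flagged.
grid_locate <- function(g, n) {
  inside <- g >= 0 & g <= (n - 1)
  i <- pmin(pmax(floor(g), 0), n - 2)
  list(i = as.integer(i), t = g - i, inside = inside)
}

# Weight matrix mapping spline coefficients (length n + 2) to values at
# grid coordinates g (length w): W %*% coef = values. deriv selects the
# derivative basis.
bspline_weights <- function(g, n, deriv = FALSE) {
  loc <- grid_locate(g, n)
  B <- if (deriv) bspline_dbasis(loc$t) else bspline_basis(loc$t)
  W <- matrix(0, length(g), n + 2L)
  for (k in 0:3) {
    idx <- cbind(seq_along(g), loc$i + 1L + k)
    W[idx] <- B[, k + 1L] * loc$inside
  }
  W
}

#' Fit a cubic-spline PSF to an averaged bead stack
#'
#' @param avg_stack 3D array `[y, x, z]`: an averaged, background-subtracted
#'   bead stack (see [average_bead_stack()]). Lateral dimensions must be odd
#'   so the PSF centre sits on a grid point.
#' @param z_values Axial positions (nm) of the slices, uniformly spaced and
#'   increasing.
#' @param spacing_xy Lateral knot spacing in pixels (default 1 knot/pixel).
#'
#' @return A `spline_psf` object. The stack is normalized so the sharpest
#'   (in-focus) slice sums to 1, making spline values photon fractions on
#'   the same contract as [evaluate_psf()].
#' @export
fit_spline <- function(avg_stack, z_values, spacing_xy = 1) {
  d <- dim(avg_stack)
  if (length(d) != 3L) stop("`avg_stack` must be [y, x, z]", call. = FALSE)
  if (any(!is.finite(avg_stack))) {
    stop("calibration error: bead stack contains non-finite values",
         call. = FALSE)
  }
  if (length(z_values) != d[3]) {
    stop("`z_values` length must match the stack depth", call. = FALSE)
  }
  dz <- diff(z_values)
  if (any(dz <= 0) || diff(range(dz)) > 1e-6 * mean(dz)) {
    stop("`z_values` must be uniformly increasing", call. = FALSE)
  }
  if (!is_odd(d[1]) || !is_odd(d[2])) {
    stop("lateral stack dimensions must be odd", call. = FALSE)
  }
  # slice with the highest peak pixel is taken as in-focus
  peaks <- apply(avg_stack, 3, max)
  norm <- sum(avg_stack[, , which.max(peaks)])
  if (!is.finite(norm) || norm <= 0) {
    stop("calibration error: in-focus slice has non-positive total",
         call. = FALSE)
  }
  stack <- avg_stack / norm

  # prefilter axis by axis: y, then x, then z
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  cy <- bspline_prefilter(matrix(stack, ny, nx * nz))          # (ny+2, nx*nz)
  a1 <- array(cy, c(ny + 2L, nx, nz))
  a1p <- aperm(a1, c(2L, 1L, 3L))                              # x first
  cx <- bspline_prefilter(matrix(a1p, nx, (ny + 2L) * nz))
  a2 <- array(cx, c(nx + 2L, ny + 2L, nz))
  a2p <- aperm(a2, c(3L, 2L, 1L))                              # z first
  cz <- bspline_prefilter(matrix(a2p, nz, (ny + 2L) * (nx + 2L)))
  coef <- aperm(array(cz, c(nz + 2L, ny + 2L, nx + 2L)), c(2L, 3L, 1L))

  structure(list(
    coef = coef, stack = stack,
    ny = ny, nx = nx, nz = nz,
    center = c((ny - 1) / 2, (nx - 1) / 2),
    spacing_xy = spacing_xy,
    z0 = z_values[1], dz = mean(dz), z_range = range(z_values),
    z_values = z_values,
    normalization = norm,
    peak = max(stack),
    format_version = 1L
  ), class = c("spline_psf", "psf_model"))
}

#' @export
print.spline_psf <- function(x, ...) {
  cat(sprintf(
    "<spline_psf> %d x %d px x %d slices | z range [%g, %g] nm (dz = %g nm)\n",
    x$ny, x$nx, x$nz, x$z_range[1], x$z_range[2], x$dz))
  invisible(x)
}

#' @export
psf_patch.spline_psf <- function(psf, x, y, z, rows, cols, pixel_size,
                                 derivatives = FALSE) {
  if (z < psf$z_range[1] || z > psf$z_range[2]) {
    stop("range error: z outside the spline z range", call. = FALSE)
  }
  sxy <- psf$spacing_xy
  gy <- (rows - y) / sxy + psf$center[1]
  gx <- (cols - x) / sxy + psf$center[2]
  gz <- (z - psf$z0) / psf$dz

  Wy <- bspline_weights(gy, psf$ny)
  Wx <- bspline_weights(gx, psf$nx)
  zl <- grid_locate(gz, psf$nz)
  Bz <- bspline_basis(zl$t)[1L, ]
  floor_val <- 1e-9 * psf$peak

  slabs <- lapply(0:3, function(k) psf$coef[, , zl$i + 1L + k])
  val <- matrix(0, length(rows), length(cols))
  Ay <- lapply(slabs, function(S) Wy %*% S)
  for (k in 1:4) val <- val + Bz[k] * (Ay[[k]] %*% t(Wx))
  clamped <- val < floor_val
  val[clamped] <- floor_val
  if (!derivatives) {
    return(list(value = val))
  }
  Wyd <- bspline_weights(gy, psf$ny, deriv = TRUE)
  Wxd <- bspline_weights(gx, psf$nx, deriv = TRUE)
  Bzd <- bspline_dbasis(zl$t)[1L, ]
  dxm <- dym <- dzm <- matrix(0, length(rows), length(cols))
  for (k in 1:4) {
    dym <- dym + Bz[k] * ((Wyd %*% slabs[[k]]) %*% t(Wx))
    dxm <- dxm + Bz[k] * (Ay[[k]] %*% t(Wxd))
    dzm <- dzm + Bzd[k] * (Ay[[k]] %*% t(Wx))
  }
  # chain rule: d(grid coord)/d(position); y, x in pixels, z in nm
  list(value = val,
       dx = -dxm / sxy,
       dy = -dym / sxy,
       dz = dzm / psf$dz)
}
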