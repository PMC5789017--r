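# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Separable 2D convolution with mirrored edges, implemented as banded
# matrix products: K_row %*% M %*% t(K_col). Kernels are 1D numeric vectors
# of odd length.
conv2_sep <- function(mat, kernel_row, kernel_col = kernel_row) {
  band_matrix <- function(n, k) {
    half <- (length(k) - 1L) / 2L
    idx <- outer(seq_len(n), seq(-half, half), `+`)
    # mirror boundary
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    b <- matrix(0, n, n)
    for (j in seq_along(k)) {
      b[cbind(seq_len(n), idx[, j])] <- b[cbind(seq_len(n), idx[, j])] + k[j]
    }
    b
  }
  kr <- band_matrix(nrow(mat), kernel_row)
  kc <- band_matrix(ncol(mat), kernel_col)
  kr %*% mat %*% t(kc)
}

# Pixel-integrated 1D Gaussian: fraction of a unit Gaussian centred at
# `center` (pixel units) falling in pixels at integer coordinates `coords`.
pixel_gauss <- function(coords, center, sigma_px) {
  stats::pnorm(coords + 0.5, center, sigma_px) -
    stats::pnorm(coords - 0.5, center, sigma_px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_odd <- function(x) x %% 2L == 1L
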