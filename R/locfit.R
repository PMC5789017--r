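#' Fitting configuration
#'
#' Collects the knobs shared by detection and fitting: the detection
#' threshold in sigma units (8 is a conservative biplane choice, 6 suits
#' quadplane data where the per-plane signal is smaller), the fit window,
#' the optimizer's iteration cap and convergence tolerance (maximum
#' absolute parameter step, in px / e- / nm as applicable), the PSF width
#' used for detection and Gaussian initialization, and the pixel size.
#'
#' @param threshold Detection threshold (sigma units), > 0.
#' @param window Odd fit window (pixels), >= 7.
#' @param max_iter Maximum optimizer iterations.
#' @param tol Convergence tolerance on the parameter step.
#' @param min_separation Minimum candidate separation (pixels).
#' @param psf_sigma PSF width (nm) for detection/initialization.
#' @param pixel_size Pixel size (nm).
#'
#' @return A `fit_config` object.
#' @export
fit_config <- function(threshold = 8, window = 15, max_iter = 100,
                       tol = 1e-4, min_separation = 3, psf_sigma = 130,
                       pixel_size = 108) {
  stopifnot(threshold > 0, window >= 7, is_odd(window))
  structure(list(threshold = threshold, window = as.integer(window),
                 max_iter = as.integer(max_iter), tol = tol,
                 min_separation = min_separation, psf_sigma = psf_sigma,
                 pixel_size = pixel_size),
            class = "fit_config")
}

#' SNSMIL-style significance map
#'
#' Matched-filter spot detection under the per-pixel camera noise model:
#' the map is the PSF-matched filter response after local background
#' subtraction, divided by the per-pixel noise scale combining the Poisson
#' variance of the local mean with the read-noise variance map. Units are
#' standard deviations, so a threshold of 8 means "8 sigma above local
#' background".
#'
#' @param frame Corrected frame (matrix, photo-electrons).
#' @param psf_sigma_px PSF width in pixels, > 0.
#' @param cal A [camera_calibration()] (supplies the read-noise map).
#'
#' @return Matrix of per-pixel significances (sigma units).
#' @export
significance_map <- function(frame, psf_sigma_px, cal) {
  if (psf_sigma_px <= 0) {
    stop("configuration error: psf_sigma_px must be > 0", call. = FALSE)
  }
  half <- max(3L, ceiling(3 * psf_sigma_px))
  k <- pixel_gauss(seq(-half, half), 0, psf_sigma_px)
  k <- k / sum(k)
  bg_half <- max(2L * half, 6L)
  box <- rep(1 / (2 * bg_half + 1), 2 * bg_half + 1)

  bg <- conv2_sep(frame, box)
  resp <- conv2_sep(frame, k) - bg
  pixvar <- pmax(bg, 0) + cal$readvar
  noise <- sqrt(pmax(conv2_sep(pixvar, k^2), 1e-12))
  resp / noise
}

#' Find candidate emitters in a significance map
#'
#' Local maxima above `threshold`; maxima closer than `min_separation`
#' keep only the larger (ties resolved toward smaller row, then column).
#'
#' @param map Significance map (matrix).
#' @param threshold Threshold (sigma units), > 0.
#' @param min_separation Minimum separation (pixels).
#'
#' @return A tibble `row`, `col` (0-based pixel indices), `value`.
#' @export
find_candidates <- function(map, threshold, min_separation = 3) {
  stopifnot(threshold > 0)
  nr <- nrow(map); nc <- ncol(map)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- map
  is_max <- map >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
    # strict on the earlier neighbour resolves plateau ties to smaller index
    if (dr < 0L || (dr == 0L && dc < 0L)) {
      is_max <- is_max & (map > nb)
    } else {
      is_max <- is_max & (map >= nb)
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(row = integer(), col = integer(),
                          value = numeric()))
  }
  cand <- tibble::tibble(row = as.integer(unname(idx[, 1])) - 1L,
                         col = as.integer(unname(idx[, 2])) - 1L,
                         value = unname(map[idx]))
  cand <- cand[order(-cand$value, cand$row, cand$col), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    keep[i] <- min(d2) >= min_separation^2
  }
  out <- cand[keep, ]
  out[order(out$row, out$col), ]
}

# ---------------------------------------------------------------------------
# Batched Gaussian MLE under the sCMOS noise model.
#
# The per-pixel read-noise variance enters as the standard
# variance-as-offset trick: data and model are both shifted by readvar and
# treated as Poisson, which reproduces the Poisson + Gaussian likelihood's
# estimating equations to second order. All spots iterate together
# (Fisher-scoring steps with per-spot Levenberg damping; a step is only
# accepted if the log-likelihood does not decrease).
# ---------------------------------------------------------------------------
gauss_mle_batch <- function(data, readvar, init, tol = 1e-4, max_iter = 100,
                            trace = FALSE) {
  n <- nrow(data)
  w <- sqrt(ncol(data))
  coords <- seq_len(w) - 1
  ri <- rep(seq_len(w), times = w)      # row index per pixel (y)
  ci <- rep(seq_len(w), each = w)       # col index per pixel (x)
  dprime <- data + readvar

  th <- init                             # columns: x, y, N, b, sigma_px
  lambda <- rep(1e-3, n)
  active <- rep(TRUE, n)
  status <- rep("failed", n)
  ll_trace <- if (trace) vector("list", n) else NULL

  model_parts <- function(th) {
    x <- th[, 1]; y <- th[, 2]; s <- th[, 5]
    cm <- matrix(coords, n, w, byrow = TRUE)
    ex_hi <- (cm + 0.5 - x) / s; ex_lo <- (cm - 0.5 - x) / s
    ey_hi <- (cm + 0.5 - y) / s; ey_lo <- (cm - 0.5 - y) / s
    Ex <- stats::pnorm(ex_hi) - stats::pnorm(ex_lo)
    Ey <- stats::pnorm(ey_hi) - stats::pnorm(ey_lo)
    phx_hi <- stats::dnorm(ex_hi); phx_lo <- stats::dnorm(ex_lo)
    phy_hi <- stats::dnorm(ey_hi); phy_lo <- stats::dnorm(ey_lo)
    list(Ex = Ex, Ey = Ey,
         dEx_dx = -(phx_hi - phx_lo) / s,
         dEy_dy = -(phy_hi - phy_lo) / s,
         dEx_ds = -(phx_hi * ex_hi - phx_lo * ex_lo) / s,
         dEy_ds = -(phy_hi * ey_hi - phy_lo * ey_lo) / s)
  }

  loglik <- function(th) {
    p <- model_parts(th)
    mu <- th[, 3] * p$Ey[, ri, drop = FALSE] * p$Ex[, ci, drop = FALSE] +
      th[, 4]
    mup <- pmax(mu + readvar, 1e-9)
    rowSums(dprime * log(mup) - mup)
  }

  ll <- loglik(th)
  if (trace) for (k in seq_len(n)) ll_trace[[k]] <- ll[k]

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    p <- model_parts(th)
    Eyr <- p$Ey[, ri, drop = FALSE]; Exc <- p$Ex[, ci, drop = FALSE]
    mu <- th[, 3] * Eyr * Exc + th[, 4]
    mup <- pmax(mu + readvar, 1e-9)
    r <- dprime / mup - 1

    d_list <- list(
      x = th[, 3] * Eyr * p$dEx_dx[, ci, drop = FALSE],
      y = th[, 3] * p$dEy_dy[, ri, drop = FALSE] * Exc,
      N = Eyr * Exc,
      b = matrix(1, n, w * w),
      s = th[, 3] * (p$dEy_ds[, ri, drop = FALSE] * Exc +
                       Eyr * p$dEx_ds[, ci, drop = FALSE])
    )
    g <- vapply(d_list, function(D) rowSums(r * D), numeric(n))
    H <- array(0, c(n, 5, 5))
    for (a in 1:5) for (b in a:5) {
      hab <- rowSums(d_list[[a]] * d_list[[b]] / mup)
      H[, a, b] <- hab
      H[, b, a] <- hab
    }

    th_new <- th
    step_size <- rep(0, n)
    for (k in which(active)) {
      Hk <- H[k, , ] + lambda[k] * diag(pmax(diag(H[k, , ]), 1e-12))
      delta <- tryCatch(solve(Hk, g[k, ]), error = function(e) rep(0, 5))
      thk <- th[k, ] + delta
      thk[3] <- max(thk[3], 1e-6)
      thk[4] <- max(thk[4], 0)
      thk[5] <- min(max(thk[5], 0.3), w)
      th_new[k, ] <- thk
      step_size[k] <- max(abs(delta))
    }
    ll_new <- loglik(th_new)
    for (k in which(active)) {
      if (ll_new[k] >= ll[k] - 1e-9) {
        th[k, ] <- th_new[k, ]
        ll[k] <- ll_new[k]
        lambda[k] <- max(lambda[k] / 10, 1e-6)
        if (trace) ll_trace[[k]] <- c(ll_trace[[k]], ll[k])
        if (step_size[k] < tol) {
          active[k] <- FALSE
          status[k] <- "converged"
        }
      } else {
        lambda[k] <- lambda[k] * 10
        if (lambda[k] > 1e8) active[k] <- FALSE   # stuck: stays "failed"
      }
    }
  }
  status[th[, 3] <= 1e-6] <- "failed"
  list(theta = th, status = status, loglik = ll, trace = ll_trace)
}

# Single-window Gaussian fit used for bead alignment (no read-noise map).
# Returns 0-based (x, y) within the window plus N, b, sigma_px.
fit_gauss_window <- function(window, sigma_px = 1.3) {
  w <- nrow(window)
  b0 <- stats::median(c(window[c(1, w), ], window[, c(1, w)]))
  sub <- pmax(window - b0, 0)
  tot <- sum(sub)
  coords <- seq_len(w) - 1
  x0 <- sum(colSums(sub) * coords) / max(tot, 1e-9)
  y0 <- sum(rowSums(sub) * coords) / max(tot, 1e-9)
  fit <- gauss_mle_batch(matrix(pmax(c(window), 0), 1),
                         matrix(0, 1, w * w),
                         matrix(c(x0, y0, max(tot, 1), max(b0, 0), sigma_px),
                                1),
                         tol = 1e-5, max_iter = 60)
  list(x = fit$theta[1, 1], y = fit$theta[1, 2], photons = fit$theta[1, 3],
       background = fit$theta[1, 4], sigma_px = fit$theta[1, 5],
       status = fit$status[1])
}

#' Single-plane Gaussian MLE fitting
#'
#' Fits each candidate with a pixel-integrated 2D Gaussian by maximum
#' likelihood under the per-pixel sCMOS noise model (Poisson shot noise
#' plus the calibration's read-noise variance). Parameters are position
#' `(x, y)`, total signal `N`, per-pixel background `b`, and Gaussian
#' width `sigma` (reported in nm). Non-converged fits are flagged, never
#' silently dropped.
#'
#' @param stack Corrected `frame_stack` (photo-electrons), or a single
#'   matrix frame.
#' @param cal A [camera_calibration()].
#' @param candidates Optional tibble (`row`, `col`, and `frame` for
#'   stacks, 0-based). When `NULL`, detection is run per frame with
#'   `config$threshold`.
#' @param config A [fit_config()].
#' @param trace Keep per-iteration log-likelihoods (attribute
#'   `"trace"` of the result; diagnostic).
#'
#' @return A [localization_table()] with columns `x`, `y`, `photons`,
#'   `background`, `sigma` (nm), `frame`, `signal_1`, `status`.
#' @export
fit_single_plane <- function(stack, cal, candidates = NULL, config = fit_config(),
                             trace = FALSE) {
  if (is.matrix(stack)) stack <- frame_stack(stack, units = "electrons")
  if (stack$units != "electrons") {
    stop("frames must be corrected to photo-electrons first", call. = FALSE)
  }
  sig_px <- config$psf_sigma / config$pixel_size
  w <- config$window
  half <- (w - 1L) / 2L
  nf <- n_frames(stack)

  if (is.null(candidates)) {
    cand_list <- lapply(seq_len(nf) - 1L, function(f) {
      m <- significance_map(stack$pixels[, , f + 1L], sig_px, cal)
      cc <- find_candidates(m, config$threshold, config$min_separation)
      cc$frame <- f
      cc
    })
    candidates <- dplyr::bind_rows(cand_list)
  } else if (!"frame" %in% names(candidates)) {
    candidates$frame <- 0L
  }
  n <- nrow(candidates)
  empty <- localization_table(
    tibble::tibble(x = numeric(), y = numeric(), photons = numeric(),
                   background = numeric(), sigma = numeric(),
                   frame = integer(), signal_1 = numeric(),
                   status = character()),
    pixel_size = config$pixel_size, n_frames = nf)
  if (n == 0L) return(empty)

  d <- dim(stack$pixels)
  in_bounds <- candidates$row - half >= 0L & candidates$row + half < d[1] &
    candidates$col - half >= 0L & candidates$col + half < d[2]

  rows_out <- vector("list", 2L)
  fit_res <- NULL
  if (any(in_bounds)) {
    cb <- candidates[in_bounds, ]
    nb <- nrow(cb)
    data <- matrix(0, nb, w * w)
    rv <- matrix(0, nb, w * w)
    init <- matrix(0, nb, 5L)
    for (k in seq_len(nb)) {
      rr <- (cb$row[k] - half):(cb$row[k] + half) + 1L
      cc <- (cb$col[k] - half):(cb$col[k] + half) + 1L
      win <- stack$pixels[rr, cc, cb$frame[k] + 1L]
      data[k, ] <- c(win)
      rv[k, ] <- c(cal$readvar[rr, cc])
      b0 <- stats::median(c(win[c(1, w), ], win[, c(1, w)]))
      sub <- pmax(win - b0, 0)
      tot <- max(sum(sub), 1)
      coords <- seq_len(w) - 1
      init[k, ] <- c(sum(colSums(sub) * coords) / tot,
                     sum(rowSums(sub) * coords) / tot,
                     tot, max(b0, 0), sig_px)
    }
    data <- pmax(data, 0)    # Poisson-likelihood data must be non-negative
    fit_res <- gauss_mle_batch(data, rv, init, tol = config$tol,
                               max_iter = config$max_iter, trace = trace)
    rows_out[[1]] <- tibble::tibble(
      x = cb$col - half + fit_res$theta[, 1],
      y = cb$row - half + fit_res$theta[, 2],
      photons = fit_res$theta[, 3],
      background = fit_res$theta[, 4],
      sigma = fit_res$theta[, 5] * config$pixel_size,
      frame = as.integer(cb$frame),
      signal_1 = fit_res$theta[, 3],
      status = fit_res$status)
  }
  if (any(!in_bounds)) {
    ce <- candidates[!in_bounds, ]
    rows_out[[2]] <- tibble::tibble(
      x = as.numeric(ce$col), y = as.numeric(ce$row), photons = NA_real_,
      background = NA_real_, sigma = NA_real_,
      frame = as.integer(ce$frame), signal_1 = NA_real_,
      status = "rejected")
  }
  out <- localization_table(dplyr::bind_rows(rows_out),
                            pixel_size = config$pixel_size, n_frames = nf)
  if (trace && !is.null(fit_res)) attr(out, "trace") <- fit_res$trace
  out
}
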