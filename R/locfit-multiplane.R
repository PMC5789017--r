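#' Joint multiplane MLE fitting with spline PSFs
#'
#' Fits emitters jointly across all planes of a biplane/quadplane (or
#' spectral) acquisition: shared position `(x, y)` in the reference frame,
#' shared axial position `z` and total signal `N`, per-plane background,
#' with the per-plane transmissions held fixed at the geometry's values.
#' Detection runs per plane on significance maps; candidates are mapped to
#' the reference frame through the geometry's affine transforms and merged
#' within `config$min_separation` before seeding a joint fit. `z` is
#' reported in nm as fitted (apply [rescale_z()] afterwards for the
#' spherical-aberration correction).
#'
#' The reported `photons` is the fitted shared total `N`; `signal_p` are
#' per-plane least-squares signal amplitudes measured at the fitted
#' position, so a plane that received no light reports a signal near zero
#' while the joint fit still converges on the remaining planes.
#'
#' @param stacks List of corrected `frame_stack`s, one per plane,
#'   time-synchronized.
#' @param cals List of [camera_calibration()] per plane (or one, reused).
#' @param psfs List of [fit_spline()] PSF models per plane (or one).
#' @param geometry A [plane_geometry()]; its transforms map each plane to
#'   the reference frame.
#' @param config A [fit_config()].
#' @param candidates Optional tibble (`x`, `y` reference-frame 0-based
#'   pixels, `frame`) to skip detection.
#' @param trace Keep per-iteration log-likelihoods for diagnostics.
#'
#' @return A [localization_table()] with `x`, `y`, `z`, `photons`,
#'   `background` (mean over planes), `frame`, `signal_1..signal_P` and
#'   `status`.
#' @export
fit_multiplane <- function(stacks, cals, psfs, geometry,
                           config = fit_config(), candidates = NULL,
                           trace = FALSE) {
  P <- geometry$n_planes
  if (inherits(cals, "camera_calibration")) cals <- rep(list(cals), P)
  if (inherits(psfs, "psf_model")) psfs <- rep(list(psfs), P)
  stopifnot(length(stacks) == P, length(cals) == P, length(psfs) == P)
  for (s in stacks) {
    if (s$units != "electrons") {
      stop("frames must be corrected to photo-electrons first", call. = FALSE)
    }
  }
  nf <- n_frames(stacks[[1]])
  sig_px <- config$psf_sigma / config$pixel_size

  if (is.null(candidates)) {
    cand_all <- vector("list", nf)
    for (f in seq_len(nf) - 1L) {
      pooled <- vector("list", P)
      for (p in seq_len(P)) {
        m <- significance_map(stacks[[p]]$pixels[, , f + 1L], sig_px,
                              cals[[p]])
        cc <- find_candidates(m, config$threshold, config$min_separation)
        if (nrow(cc) == 0L) next
        pos <- cbind(cc$col, cc$row)
        tr <- geometry$transforms[[p]]
        if (!is.null(tr)) pos <- apply_affine(tr, pos)
        pooled[[p]] <- tibble::tibble(x = pos[, 1], y = pos[, 2],
                                      value = cc$value)
      }
      pool <- dplyr::bind_rows(pooled)
      if (nrow(pool) == 0L) next
      pool <- pool[order(-pool$value), ]
      keep <- logical(nrow(pool))
      for (i in seq_len(nrow(pool))) {
        if (!any(keep)) {
          keep[i] <- TRUE
          next
        }
        d2 <- (pool$x[keep] - pool$x[i])^2 + (pool$y[keep] - pool$y[i])^2
        keep[i] <- min(d2) >= config$min_separation^2
      }
      cand_all[[f + 1L]] <- tibble::tibble(x = pool$x[keep],
                                           y = pool$y[keep], frame = f)
    }
    candidates <- dplyr::bind_rows(cand_all)
  }

  empty <- localization_table(
    tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                   photons = numeric(), background = numeric(),
                   sigma = numeric(), frame = integer(),
                   status = character()),
    pixel_size = config$pixel_size, geometry_id = geometry$id,
    n_frames = nf)
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)

  res <- vector("list", nrow(candidates))
  traces <- if (trace) vector("list", nrow(candidates)) else NULL
  for (k in seq_len(nrow(candidates))) {
    fit <- fit_multiplane_one(
      candidates$x[k], candidates$y[k], candidates$frame[k],
      stacks, cals, psfs, geometry, config, trace)
    res[[k]] <- fit$row
    if (trace) traces[[k]] <- fit$trace
  }
  out <- localization_table(dplyr::bind_rows(res),
                            pixel_size = config$pixel_size,
                            geometry_id = geometry$id, n_frames = nf)
  if (trace) attr(out, "trace") <- traces
  out
}

# One joint fit. Returns list(row = tibble row, trace = numeric).
fit_multiplane_one <- function(x0, y0, frame, stacks, cals, psfs, geometry,
                               config, trace = FALSE) {
  P <- geometry$n_planes
  w <- config$window
  half <- (w - 1L) / 2L
  px <- config$pixel_size
  tp <- geometry$transmissions

  reject_row <- function(status) {
    row <- tibble::tibble(x = x0, y = y0, z = NA_real_, photons = NA_real_,
                          background = NA_real_, sigma = NA_real_,
                          frame = as.integer(frame), status = status)
    for (p in seq_len(P)) row[[paste0("signal_", p)]] <- NA_real_
    list(row = row, trace = numeric())
  }

  # per-plane window geometry
  Ai <- vector("list", P)
  pos_p <- matrix(0, P, 2)
  rows_p <- cols_p <- vector("list", P)
  data_p <- rv_p <- vector("list", P)
  b0 <- numeric(P)
  for (p in seq_len(P)) {
    tr <- geometry$transforms[[p]]
    if (is.null(tr)) {
      Ai[[p]] <- diag(2)
      pos_p[p, ] <- c(x0, y0)
    } else {
      inv <- invert_affine(tr)
      Ai[[p]] <- inv$A
      pos_p[p, ] <- drop(apply_affine(inv, c(x0, y0)))
    }
    ctr <- round(pos_p[p, ])
    d <- dim(stacks[[p]]$pixels)
    if (ctr[2] - half < 0 || ctr[2] + half >= d[1] ||
        ctr[1] - half < 0 || ctr[1] + half >= d[2]) {
      return(reject_row("rejected"))
    }
    rows_p[[p]] <- (ctr[2] - half):(ctr[2] + half)
    cols_p[[p]] <- (ctr[1] - half):(ctr[1] + half)
    win <- stacks[[p]]$pixels[rows_p[[p]] + 1L, cols_p[[p]] + 1L,
                              frame + 1L]
    data_p[[p]] <- pmax(win, 0)
    rv_p[[p]] <- cals[[p]]$readvar[rows_p[[p]] + 1L, cols_p[[p]] + 1L]
    b0[p] <- max(stats::median(c(win[c(1, w), ], win[, c(1, w)])), 0)
  }

  # z initialization: coarse scan of the spline slices, matched-filter score.
  # The usable absolute-z range keeps every plane's defocus inside the
  # spline support: z - offset_p must stay within z_range for all p.
  zr <- psfs[[1]]$z_range
  dz <- psfs[[1]]$dz
  z_lo <- zr[1] + max(geometry$focal_offsets) + dz
  z_hi <- zr[2] + min(geometry$focal_offsets) - dz
  if (z_hi <= z_lo) {
    stop("configuration error: spline z range shorter than the plane span",
         call. = FALSE)
  }
  z_grid <- seq(z_lo, z_hi, length.out = min(21L, psfs[[1]]$nz))
  best <- list(score = -Inf, z = 0, N = 1000)
  for (z in z_grid) {
    num <- 0; den <- 0
    for (p in seq_len(P)) {
      u <- tp[p] * psf_patch(psfs[[p]], pos_p[p, 1], pos_p[p, 2],
                             z - geometry$focal_offsets[p],
                             rows_p[[p]], cols_p[[p]], px)$value
      num <- num + sum((data_p[[p]] - b0[p]) * u)
      den <- den + sum(u^2)
    }
    score <- num / sqrt(den)
    if (score > best$score) best <- list(score = score, z = z,
                                         N = max(num / den, 1))
  }

  np <- 4L + P
  th <- c(x0, y0, best$z, best$N, b0)
  dpr <- lapply(seq_len(P), function(p) data_p[[p]] + rv_p[[p]])

  eval_model <- function(th, derivatives = FALSE) {
    out <- vector("list", P)
    for (p in seq_len(P)) {
      ppos <- Ai[[p]] %*% (c(th[1], th[2]) - 0) +
        (pos_p[p, ] - Ai[[p]] %*% c(x0, y0))   # affine: Ai %*% pos + const
      zp <- th[3] - geometry$focal_offsets[p]
      if (zp < zr[1] || zp > zr[2]) return(NULL)
      out[[p]] <- psf_patch(psfs[[p]], ppos[1], ppos[2], zp,
                            rows_p[[p]], cols_p[[p]], px,
                            derivatives = derivatives)
      out[[p]]$pos <- ppos
    }
    out
  }

  loglik <- function(th, patches = NULL) {
    if (is.null(patches)) patches <- eval_model(th)
    if (is.null(patches)) return(-Inf)
    ll <- 0
    for (p in seq_len(P)) {
      mu <- tp[p] * th[4] * patches[[p]]$value + th[4L + p]
      mup <- pmax(mu + rv_p[[p]], 1e-9)
      ll <- ll + sum(dpr[[p]] * log(mup) - mup)
    }
    ll
  }

  lambda <- 1e-3
  ll <- loglik(th)
  ll_tr <- ll
  status <- "failed"
  z_clamped <- FALSE
  for (iter in seq_len(config$max_iter)) {
    patches <- eval_model(th, derivatives = TRUE)
    if (is.null(patches)) break
    g <- numeric(np)
    H <- matrix(0, np, np)
    for (p in seq_len(P)) {
      pa <- patches[[p]]
      mu <- tp[p] * th[4] * pa$value + th[4L + p]
      mup <- pmax(mu + rv_p[[p]], 1e-9)
      r <- dpr[[p]] / mup - 1
      D <- matrix(0, length(mu), np)
      scale <- tp[p] * th[4]
      D[, 1] <- c(scale * (pa$dx * Ai[[p]][1, 1] + pa$dy * Ai[[p]][2, 1]))
      D[, 2] <- c(scale * (pa$dx * Ai[[p]][1, 2] + pa$dy * Ai[[p]][2, 2]))
      D[, 3] <- c(scale * pa$dz)
      D[, 4] <- c(tp[p] * pa$value)
      D[, 4L + p] <- 1
      g <- g + colSums(c(r) * D)
      H <- H + crossprod(D, D / c(mup))
    }
    Hd <- H + lambda * diag(pmax(diag(H), 1e-12), np)
    delta <- tryCatch(solve(Hd, g), error = function(e) NULL)
    if (is.null(delta)) break
    th_new <- th + delta
    z_clamped <- th_new[3] <= z_lo || th_new[3] >= z_hi
    th_new[3] <- min(max(th_new[3], z_lo), z_hi)
    th_new[4] <- max(th_new[4], 1e-6)
    th_new[5:np] <- pmax(th_new[5:np], 0)
    ll_new <- loglik(th_new)
    if (ll_new >= ll - 1e-9) {
      step <- max(abs(th_new - th))
      th <- th_new
      ll <- ll_new
      lambda <- max(lambda / 10, 1e-6)
      if (trace) ll_tr <- c(ll_tr, ll)
      if (step < config$tol) {
        status <- if (z_clamped) "failed" else "converged"
        break
      }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
  }
  if (th[4] <= 1e-6) status <- "failed"

  # per-plane measured signal amplitudes at the fitted position: least
  # squares with a free flat background per plane, so a plane that received
  # no light reports ~0 regardless of how the joint fit compromised
  patches <- eval_model(th)
  signals <- rep(NA_real_, P)
  if (!is.null(patches)) {
    for (p in seq_len(P)) {
      u <- c(patches[[p]]$value)
      d <- c(data_p[[p]])
      uc <- u - mean(u)
      signals[p] <- sum((d - mean(d)) * uc) / max(sum(uc^2), 1e-12)
    }
  }
  row <- tibble::tibble(x = th[1], y = th[2], z = th[3], photons = th[4],
                        background = mean(th[5:np]), sigma = NA_real_,
                        frame = as.integer(frame), status = status)
  for (p in seq_len(P)) row[[paste0("signal_", p)]] <- signals[p]
  list(row = row, trace = ll_tr)
}
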