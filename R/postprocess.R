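#' Track beads across frames
#'
#' Localizations in frame 0 seed one track each; every later localization
#' joins the track whose seed position is nearest, provided it lies within
#' `radius` pixels. Seeds are fixed at their frame-0 positions. When two
#' localizations in one frame match the same seed, the nearer one is kept
#' and the other flagged ambiguous.
#'
#' @param table A [localization_table()] containing frame 0.
#' @param radius Assignment radius (pixels).
#'
#' @return The table with added columns `track` (seed index, `NA` if
#'   unassigned) and `ambiguous`.
#' @export
track_beads <- function(table, radius = 2) {
  stopifnot(radius > 0)
  seeds <- table[table$frame == 0L, c("x", "y")]
  if (nrow(seeds) == 0L) {
    stop("frame 0 has no localizations to seed tracks", call. = FALSE)
  }
  track <- rep(NA_integer_, nrow(table))
  ambiguous <- rep(FALSE, nrow(table))
  d2 <- outer(table$x, seeds$x, `-`)^2 + outer(table$y, seeds$y, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  nd <- sqrt(d2[cbind(seq_len(nrow(table)), nearest)])
  within <- nd <= radius
  track[within] <- nearest[within]
  # per frame, one localization per seed: keep the nearest
  for (f in unique(table$frame)) {
    idx <- which(table$frame == f & !is.na(track))
    if (length(idx) < 2L) next
    for (s in unique(track[idx])) {
      dup <- idx[track[idx] == s]
      if (length(dup) > 1L) {
        loser <- dup[dup != dup[which.min(nd[dup])]]
        track[loser] <- NA_integer_
        ambiguous[c(dup)] <- TRUE
      }
    }
  }
  out <- table
  out$track <- track
  out$ambiguous <- ambiguous
  restore_table(out, table)
}

#' Filter tracks by missing-frame fraction
#'
#' A track is kept iff it is missing from at most `max_missing` of the
#' movie's frames (strictly more than the fraction discards, so 10 missing
#' out of 100 frames survives a 10% cut and 11 does not). With `paired`
#' (the same beads tracked on a second camera) a track must pass on both.
#'
#' @param table Output of [track_beads()].
#' @param movie_length Movie length (frames), > 0.
#' @param max_missing Maximum tolerated missing fraction.
#' @param paired Optional second tracked table; track ids must correspond.
#'
#' @return The table restricted to surviving tracks.
#' @export
filter_tracks <- function(table, movie_length, max_missing = 0.10,
                          paired = NULL) {
  stopifnot(movie_length > 0)
  passing <- function(tbl) {
    ids <- sort(unique(stats::na.omit(tbl$track)))
    present <- vapply(ids, function(s) {
      length(unique(tbl$frame[!is.na(tbl$track) & tbl$track == s]))
    }, integer(1))
    ids[(movie_length - present) <= max_missing * movie_length]
  }
  keep <- passing(table)
  if (!is.null(paired)) keep <- intersect(keep, passing(paired))
  out <- table[!is.na(table$track) & table$track %in% keep, ]
  restore_table(out, table)
}

#' Per-track precision statistics
#'
#' Sample standard deviations of the fitted positions (converted to nm
#' with the table's pixel size; unbiased n-1 estimator) and means of the
#' fitted signal and background, per track. Tracks shorter than 10 frames
#' are flagged `insufficient`.
#'
#' @param table Output of [track_beads()] (optionally filtered).
#'
#' @return A tibble: `track`, `n`, `std_x`, `std_y`, `std_z` (nm),
#'   `mean_photons`, `mean_background`, `insufficient`.
#' @export
precision_stats <- function(table) {
  a <- attr(table, "pixel_size")
  df <- as.data.frame(table)
  df <- df[!is.na(df$track), ]
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$track),
    n = dplyr::n(),
    std_x = stats::sd(.data$x) * a,
    std_y = stats::sd(.data$y) * a,
    std_z = if ("z" %in% names(df)) stats::sd(.data$z) else NA_real_,
    mean_photons = mean(.data$photons),
    mean_background = mean(.data$background),
    .groups = "drop")
  out$insufficient <- out$n < 10L
  tibble::as_tibble(out)
}

# FFT cross-correlation offset between two equally-binned histograms,
# with 3-point quadratic sub-bin interpolation. Returns (drow, dcol) such
# that shifting `img` by it aligns it to `ref`.
xcorr_offset <- function(ref, img) {
  F1 <- stats::fft(ref)
  F2 <- stats::fft(img)
  cc <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  n <- dim(cc)
  sub <- function(axis) {
    i <- pk[axis]
    ip <- i %% n[axis] + 1L
    im <- (i - 2L) %% n[axis] + 1L
    c0 <- if (axis == 1L) cc[i, pk[2]] else cc[pk[1], i]
    cp <- if (axis == 1L) cc[ip, pk[2]] else cc[pk[1], ip]
    cm <- if (axis == 1L) cc[im, pk[2]] else cc[pk[1], im]
    denom <- cm - 2 * c0 + cp
    frac <- if (abs(denom) > 1e-12) 0.5 * (cm - cp) / denom else 0
    d <- (i - 1L) + frac
    if (d > n[axis] / 2) d <- d - n[axis]
    -d                      # peak at -shift: report the shift of img vs ref
  }
  c(sub(1L), sub(2L))
}

#' Drift correction by sub-image cross-correlation
#'
#' Splits the movie into consecutive segments of `segment_frames`, renders
#' each segment to a 2D histogram at `bin_size_nm`, estimates each
#' segment's lateral offset relative to the first by the cross-correlation
#' peak (with sub-bin quadratic interpolation), linearly interpolates
#' offsets between segment centres, and subtracts the per-frame drift.
#' Segments with fewer than 100 localizations get offsets interpolated
#' from their neighbours (with a warning). Optionally also corrects z via
#' 1D histogram cross-correlation.
#'
#' @param table A [localization_table()] spanning >= 2 segments.
#' @param segment_frames Segment length (frames).
#' @param bin_size_nm Histogram bin size (nm).
#' @param correct_z Also estimate and subtract z drift (needs a `z`
#'   column).
#'
#' @return List with `table` (corrected) and `drift` (tibble `segment`,
#'   `frame_mid`, `dx`, `dy`, `dz` in nm; first segment anchored at 0).
#' @export
drift_correct <- function(table, segment_frames = 1000, bin_size_nm = 20,
                          correct_z = FALSE) {
  meta <- loc_metadata(table)
  a <- meta$pixel_size
  nseg <- ceiling(meta$n_frames / segment_frames)
  if (nseg < 2L) {
    stop("movie spans fewer than 2 drift segments", call. = FALSE)
  }
  seg <- pmin(table$frame %/% segment_frames, nseg - 1L) + 1L
  xs <- table$x * a
  ys <- table$y * a
  xr <- range(xs); yr <- range(ys)
  bx <- seq(xr[1], xr[2] + bin_size_nm, by = bin_size_nm)
  by <- seq(yr[1], yr[2] + bin_size_nm, by = bin_size_nm)
  hist2 <- function(idx) {
    ix <- findInterval(xs[idx], bx, rightmost.closed = TRUE)
    iy <- findInterval(ys[idx], by, rightmost.closed = TRUE)
    m <- matrix(0, length(by) - 1L, length(bx) - 1L)
    for (k in seq_along(idx)) m[iy[k], ix[k]] <- m[iy[k], ix[k]] + 1
    m
  }
  counts <- tabulate(seg, nseg)
  low <- counts < 100L
  if (any(low)) {
    warning(sum(low), " segment(s) with <100 localizations; offsets ",
            "interpolated from neighbours", call. = FALSE)
  }
  ref_idx <- which(seg == 1L)
  ref <- hist2(ref_idx)
  off <- matrix(NA_real_, nseg, 3L)
  off[1, ] <- 0
  zb <- NULL
  if (correct_z) {
    zr <- range(table$z)
    zb <- seq(zr[1], zr[2] + bin_size_nm, by = bin_size_nm)
  }
  for (s in seq_len(nseg)[-1]) {
    if (low[s]) next
    idx <- which(seg == s)
    d <- xcorr_offset(ref, hist2(idx))
    off[s, 1] <- d[2] * bin_size_nm     # dx from column shift
    off[s, 2] <- d[1] * bin_size_nm
    off[s, 3] <- if (correct_z) {
      h1 <- tabulate(findInterval(table$z[ref_idx], zb,
                                  rightmost.closed = TRUE), length(zb) - 1L)
      h2 <- tabulate(findInterval(table$z[idx], zb,
                                  rightmost.closed = TRUE), length(zb) - 1L)
      xcorr_offset(matrix(h1, 1), matrix(h2, 1))[2] * bin_size_nm
    } else {
      0
    }
  }
  # fill skipped segments by interpolation over segment index
  for (j in 1:3) {
    known <- which(!is.na(off[, j]))
    off[, j] <- stats::approx(known, off[known, j], xout = seq_len(nseg),
                              rule = 2)$y
  }
  mids <- (seq_len(nseg) - 0.5) * segment_frames
  drift <- tibble::tibble(segment = seq_len(nseg) - 1L, frame_mid = mids,
                          dx = off[, 1], dy = off[, 2], dz = off[, 3])
  per_frame <- function(j) {
    stats::approx(mids, off[, j], xout = table$frame, rule = 2)$y
  }
  out <- table
  out$x <- out$x - per_frame(1) / a
  out$y <- out$y - per_frame(2) / a
  if (correct_z) out$z <- out$z - per_frame(3)
  list(table = restore_table(out, table), drift = drift)
}

#' Rescale fitted z positions
#'
#' Multiplies z by `factor` — the first-order correction for the axial
#' compression caused by spherical aberration at a refractive-index
#' mismatch (0.79 for oil immersion into aqueous samples). The factor is
#' recorded in the table's metadata; rescaling is linear, so ordering and
#' relative spacing of z values are preserved.
#'
#' @param table A [localization_table()] with a `z` column.
#' @param factor Rescale factor.
#' @return The rescaled table.
#' @examples
#' # z = 1000 nm -> 790 nm at the default factor
#' @export
rescale_z <- function(table, factor = 0.79) {
  if (!"z" %in% names(table)) stop("table has no z column", call. = FALSE)
  out <- table
  out$z <- out$z * factor
  out <- restore_table(out, table)
  attr(out, "z_rescale") <- factor * (attr(table, "z_rescale") %||% 1)
  out
}

#' Render a localization table to a super-resolution image
#'
#' Histogram mode bins localization counts at `bin_size_nm`; Gaussian mode
#' splats each localization as a unit-integral Gaussian of width
#' `blob_sigma_nm`. With `z_color` the result is an RGB array with hue
#' encoding z.
#'
#' @param table A [localization_table()].
#' @param bin_size_nm Bin size (nm), > 0.
#' @param mode `"hist"` or `"gaussian"`.
#' @param blob_sigma_nm Blob width for Gaussian mode (nm).
#' @param z_color Color-code z (returns `[h, w, 3]` RGB array).
#'
#' @return A matrix (counts/intensity) or RGB array, with attributes
#'   `bin_size_nm` and `extent_nm`.
#' @export
render <- function(table, bin_size_nm, mode = c("hist", "gaussian"),
                   blob_sigma_nm = NULL, z_color = FALSE) {
  stopifnot(bin_size_nm > 0)
  mode <- match.arg(mode)
  a <- attr(table, "pixel_size")
  if (nrow(table) == 0L) {
    img <- matrix(0, 0, 0)
    attr(img, "bin_size_nm") <- bin_size_nm
    return(img)
  }
  xs <- table$x * a
  ys <- table$y * a
  x0 <- min(xs); y0 <- min(ys)
  nxb <- max(1L, ceiling((max(xs) - x0) / bin_size_nm + 1e-9))
  nyb <- max(1L, ceiling((max(ys) - y0) / bin_size_nm + 1e-9))
  ix <- pmin(floor((xs - x0) / bin_size_nm) + 1L, nxb)
  iy <- pmin(floor((ys - y0) / bin_size_nm) + 1L, nyb)
  img <- matrix(0, nyb, nxb)
  if (mode == "hist") {
    for (k in seq_along(ix)) img[iy[k], ix[k]] <- img[iy[k], ix[k]] + 1
  } else {
    s <- (blob_sigma_nm %||% (2 * bin_size_nm)) / bin_size_nm
    halo <- ceiling(3 * s)
    for (k in seq_along(ix)) {
      rr <- max(1L, iy[k] - halo):min(nyb, iy[k] + halo)
      cc <- max(1L, ix[k] - halo):min(nxb, ix[k] + halo)
      gy <- pixel_gauss(rr - 0.5, (ys[k] - y0) / bin_size_nm, s)
      gx <- pixel_gauss(cc - 0.5, (xs[k] - x0) / bin_size_nm, s)
      img[rr, cc] <- img[rr, cc] + outer(gy, gx)
    }
  }
  if (z_color && "z" %in% names(table)) {
    zn <- (table$z - min(table$z)) / max(diff(range(table$z)), 1e-9)
    rgb <- array(0, c(nyb, nxb, 3))
    cols <- grDevices::rainbow(256, end = 0.7)[pmin(floor(zn * 255) + 1L, 256L)]
    crgb <- grDevices::col2rgb(cols) / 255
    for (k in seq_along(ix)) {
      for (ch in 1:3) {
        rgb[iy[k], ix[k], ch] <- rgb[iy[k], ix[k], ch] + crgb[ch, k]
      }
    }
    mx <- max(rgb)
    if (mx > 0) rgb <- rgb / mx
    attr(rgb, "bin_size_nm") <- bin_size_nm
    return(rgb)
  }
  attr(img, "bin_size_nm") <- bin_size_nm
  attr(img, "extent_nm") <- c(x0, y0)
  img
}
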