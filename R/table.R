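#' Localization tables
#'
#' A localization table is a tibble of fitted emitter records carrying the
#' acquisition metadata needed downstream (pixel size, plane geometry id,
#' movie length). Required columns are `x`, `y` (sub-pixel position in the
#' reference camera frame, 0-based pixels) and `frame` (0-based index);
#' typical fits add `z` (nm), `photons` (total fitted signal, e-),
#' `background` (e- per pixel per plane), `sigma` (fitted Gaussian width,
#' nm; `NA` for spline fits), per-plane signals `signal_1..signal_k` and a
#' `status` column (`"converged"`, `"failed"` or `"rejected"`).
#'
#' @param records Data frame of localization records.
#' @param pixel_size Pixel size (nm), > 0.
#' @param geometry_id Plane-geometry label.
#' @param n_frames Movie length (frames); frame indices must lie in
#'   `[0, n_frames)`.
#'
#' @return A tibble with class `localization_table`.
#' @export
localization_table <- function(records, pixel_size, geometry_id = "single",
                               n_frames = NULL) {
  stopifnot(pixel_size > 0)
  tbl <- tibble::as_tibble(records)
  req <- c("x", "y", "frame")
  if (!all(req %in% names(tbl))) {
    stop("records need columns x, y, frame", call. = FALSE)
  }
  if (is.null(n_frames)) n_frames <- max(tbl$frame, 0L) + 1L
  if (nrow(tbl) && (any(tbl$frame < 0) || any(tbl$frame >= n_frames))) {
    stop("frame indices must lie in [0, n_frames)", call. = FALSE)
  }
  structure(tbl,
            class = c("localization_table", class(tibble::tibble())),
            pixel_size = pixel_size, geometry_id = geometry_id,
            n_frames = as.integer(n_frames))
}

#' @rdname localization_table
#' @param table A `localization_table`.
#' @export
loc_metadata <- function(table) {
  list(pixel_size = attr(table, "pixel_size"),
       geometry_id = attr(table, "geometry_id"),
       n_frames = attr(table, "n_frames"))
}

# Rebuild the class/attributes after dplyr verbs strip them.
restore_table <- function(tbl, template) {
  meta <- loc_metadata(template)
  localization_table(tbl, pixel_size = meta$pixel_size,
                     geometry_id = meta$geometry_id,
                     n_frames = meta$n_frames)
}

signal_columns <- function(table) {
  grep("^signal_[0-9]+$", names(table), value = TRUE)
}
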