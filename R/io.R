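#' Read and write camera movies as multi-page TIFF
#'
#' Raw movies are stored as 16-bit unsigned multi-page TIFF, one page per
#' frame. `write_movie()` accepts a `frame_stack` in ADU; the write/read
#' round trip is lossless for values in `[0, 65535]`.
#'
#' @param stack A `frame_stack` in ADU.
#' @param path Output/input file path.
#'
#' @return `read_movie()` returns a `frame_stack` in ADU.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$units != "adu") {
    stop("movies are written as raw ADU; correct after reading instead",
         call. = FALSE)
  }
  if (any(stack$pixels > 65535)) {
    stop("ADU values exceed the 16-bit range", call. = FALSE)
  }
  pages <- lapply(seq_len(n_frames(stack)),
                  function(i) stack$pixels[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie
#' @param camera_id Camera label attached to the returned stack.
#' @export
read_movie <- function(path, camera_id = "cam0") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop("parse error reading TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d)) {
      stop("parse error: frame ", i, " has inconsistent shape", call. = FALSE)
    }
  }
  arr <- array(0L, c(d, length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  frame_stack(arr, units = "adu", camera_id = camera_id)
}

table_magic <- "#mvsmlm-localization-table"

#' Read and write localization tables
#'
#' Tables are stored as a self-describing text container: a JSON metadata
#' header (commented lines carrying pixel size, geometry id, movie length
#' and the record count) followed by a CSV body whose header row names the
#' fields of the localization records. The record count makes truncated
#' files detectable: `read_table()` refuses to return a partial table.
#'
#' @param table A [localization_table()].
#' @param path File path.
#'
#' @return `read_table()` returns a `localization_table`.
#' @export
write_table <- function(table, path) {
  meta <- loc_metadata(table)
  meta$n_records <- nrow(table)
  header <- c(table_magic,
              paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != table_magic) {
    stop("parse error: '", path, "' is not a localization table",
         call. = FALSE)
  }
  meta <- tryCatch(jsonlite::fromJSON(sub("^# ", "", lines[2])),
                   error = function(e) {
                     stop("parse error in metadata header of '", path, "'",
                          call. = FALSE)
                   })
  body <- lines[-(1:2)]
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) {
      stop("parse error in record ", length(body) - 1L, " of '", path, "'",
           call. = FALSE)
    })
  if (nrow(df) != meta$n_records) {
    stop(sprintf(
      "parse error: '%s' truncated at record %d of %d; no partial table returned",
      path, nrow(df), meta$n_records), call. = FALSE)
  }
  localization_table(df, pixel_size = meta$pixel_size,
                     geometry_id = meta$geometry_id,
                     n_frames = meta$n_frames)
}

#' Serialize calibrations, transforms and PSF models
#'
#' Small model objects are stored as JSON: calibration maps (one entry per
#' map), affine transforms (6 numbers + direction tag) and spline PSFs
#' (coefficient grid, knot spacing, z range, normalization and a format
#' version).
#'
#' @param x Object to write.
#' @param path File path.
#' @return The read functions return the reconstructed object.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "camera_calibration"))
  jsonlite::write_json(
    list(kind = "camera_calibration", shape = x$shape,
         offset = x$offset, gain = x$gain, readvar = x$readvar),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$kind, "camera_calibration")) {
    stop("parse error: not a calibration file", call. = FALSE)
  }
  camera_calibration(j$offset, j$gain, j$readvar, shape = j$shape)
}

#' @rdname write_calibration
#' @export
write_affine <- function(x, path) {
  stopifnot(inherits(x, "affine2d"))
  jsonlite::write_json(
    list(kind = "affine2d", A = x$A, t = x$t, direction = x$direction),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_affine <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$kind, "affine2d")) {
    stop("parse error: not an affine transform file", call. = FALSE)
  }
  affine2d(j$A, j$t, direction = j$direction)
}

#' @rdname write_calibration
#' @export
write_spline_psf <- function(x, path) {
  stopifnot(inherits(x, "spline_psf"))
  jsonlite::write_json(
    list(kind = "spline_psf", format_version = x$format_version,
         stack = as.vector(x$stack), dims = c(x$ny, x$nx, x$nz),
         spacing_xy = x$spacing_xy, z_values = x$z_values,
         normalization = x$normalization),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_spline_psf <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$kind, "spline_psf")) {
    stop("parse error: not a spline PSF file", call. = FALSE)
  }
  psf <- fit_spline(array(j$stack, j$dims), j$z_values,
                    spacing_xy = j$spacing_xy)
  psf$normalization <- j$normalization
  psf
}
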