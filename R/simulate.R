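#' Plane geometry for biplane / quadplane / spectral setups
#'
#' Describes how emitted light is split over cameras: per-plane focal
#' offsets (nm), per-plane transmission fractions (must sum to 1), and the
#' affine transform mapping each secondary camera to the reference camera.
#' The presets reflect typical configurations: biplane planes ~600 nm
#' apart at 50/50 splitting, quadplane planes ~500 nm apart at 1/4 each,
#' and a 4-channel spectral geometry with ~100 nm focal offsets where the
#' transmissions are the dichroic fractions.
#'
#' @param focal_offsets Per-plane focal plane positions (nm), strictly
#'   increasing.
#' @param transmissions Per-plane signal fractions, summing to 1.
#' @param transforms List of [affine2d()] per plane (entry for the
#'   reference plane may be `NULL` = identity).
#' @param id Geometry label.
#'
#' @return A `plane_geometry` object.
#' @examples
#' biplane_geometry()
#' quadplane_geometry()
#' @export
plane_geometry <- function(focal_offsets, transmissions,
                           transforms = NULL, id = "custom") {
  n <- length(focal_offsets)
  if (!n %in% c(1L, 2L, 4L)) {
    stop("configuration error: 1, 2 or 4 planes supported", call. = FALSE)
  }
  if (length(transmissions) != n) {
    stop("configuration error: one transmission per plane", call. = FALSE)
  }
  if (abs(sum(transmissions) - 1) > 1e-9) {
    stop("configuration error: transmissions must sum to 1", call. = FALSE)
  }
  if (n > 1L && any(diff(focal_offsets) <= 0)) {
    stop("configuration error: focal offsets must be strictly increasing",
         call. = FALSE)
  }
  if (is.null(transforms)) transforms <- vector("list", n)
  structure(list(n_planes = n, focal_offsets = focal_offsets,
                 transmissions = transmissions, transforms = transforms,
                 id = id),
            class = "plane_geometry")
}

#' @rdname plane_geometry
#' @param spacing Plane spacing (nm).
#' @export
biplane_geometry <- function(spacing = 600) {
  plane_geometry(c(-spacing / 2, spacing / 2), c(0.5, 0.5), id = "biplane")
}

#' @rdname plane_geometry
#' @export
quadplane_geometry <- function(spacing = 500) {
  plane_geometry(spacing * c(-1.5, -0.5, 0.5, 1.5), rep(0.25, 4),
                 id = "quadplane")
}

#' @rdname plane_geometry
#' @param dichroic_fractions Per-channel signal fractions for the spectral
#'   geometry (default equal split).
#' @export
spectral_geometry <- function(spacing = 100,
                              dichroic_fractions = rep(0.25, 4)) {
  plane_geometry(spacing * c(-1.5, -0.5, 0.5, 1.5), dichroic_fractions,
                 id = "spectral")
}

#' @export
print.plane_geometry <- function(x, ...) {
  cat(sprintf("<plane_geometry> %s | %d plane(s) at [%s] nm, transmissions [%s]\n",
              x$id, x$n_planes,
              paste(signif(x$focal_offsets, 4), collapse = ", "),
              paste(signif(x$transmissions, 4), collapse = ", ")))
  invisible(x)
}

#' Emitter ground truth for simulations
#'
#' @param x,y Position (pixels, 0-based, reference frame).
#' @param z Axial position (nm).
#' @param photons Emitted signal per frame (photo-electrons), > 0.
#' @param on_frames Integer vector of frames (0-based) the emitter is on.
#' @param dye Dye id for spectral runs.
#'
#' @return A tibble with one row per emitter and an `on_frames`
#'   list-column.
#' @export
emitters <- function(x, y, z = 0, photons, on_frames, dye = NA_integer_) {
  if (!is.list(on_frames)) on_frames <- list(on_frames)
  stopifnot(all(photons > 0))
  tibble::tibble(x = x, y = y, z = z, photons = photons,
                 on_frames = on_frames, dye = dye)
}

# Expected photo-electron image of one plane for one frame.
expected_plane_image <- function(em_rows, psf, geom, plane, shape,
                                 background, pixel_size) {
  mu <- matrix(background, shape[1], shape[2])
  tr <- geom$transforms[[plane]]
  tp <- geom$transmissions[plane]
  dz <- geom$focal_offsets[plane]
  for (k in seq_len(nrow(em_rows))) {
    pos <- c(em_rows$x[k], em_rows$y[k])
    if (!is.null(tr)) pos <- drop(apply_affine(invert_affine(tr), pos))
    half <- 10L
    rows <- round(pos[2]) + seq(-half, half)
    cols <- round(pos[1]) + seq(-half, half)
    ok_r <- rows >= 0L & rows < shape[1]
    ok_c <- cols >= 0L & cols < shape[2]
    if (pos[1] < 0 || pos[1] >= shape[2] || pos[2] < 0 ||
        pos[2] >= shape[1]) {
      warning("emitter outside frame bounds; rendering clipped",
              call. = FALSE)
    }
    if (!any(ok_r) || !any(ok_c)) next
    patch <- psf_patch(psf, pos[1], pos[2], em_rows$z[k] - dz,
                       rows[ok_r], cols[ok_c], pixel_size)$value
    idx_r <- rows[ok_r] + 1L
    idx_c <- cols[ok_c] + 1L
    mu[idx_r, idx_c] <- mu[idx_r, idx_c] + tp * em_rows$photons[k] * patch
  }
  mu
}

# Poisson + gain/offset + Gaussian read noise, rounded to integer ADU.
render_adu <- function(mu, cal) {
  n <- length(mu)
  counts <- stats::rpois(n, lambda = c(mu))
  adu <- counts * c(cal$gain) + c(cal$offset) +
    stats::rnorm(n, sd = sqrt(c(cal$readvar)) * c(cal$gain))
  matrix(pmax(round(adu), 0), nrow(mu), ncol(mu))
}

#' Simulate a multi-camera SMLM movie
#'
#' Renders each plane's expected photo-electron image (background plus
#' PSF-spread emitter signal scaled by the plane's transmission and
#' defocused by its focal offset), then applies the full camera model:
#' Poisson shot noise, gain and offset, and per-pixel Gaussian read noise.
#' Identical inputs and seed give bit-identical output.
#'
#' @param emitters Tibble from [emitters()]; positions in the reference
#'   frame.
#' @param psf A PSF model ([gaussian_psf()] or [fit_spline()]).
#' @param geometry A [plane_geometry()].
#' @param cal A [camera_calibration()] or a list of one per plane.
#' @param background Background (e-/pixel/frame per plane); scalar or
#'   per-plane vector.
#' @param n_frames Movie length.
#' @param seed RNG seed (mandatory).
#' @param pixel_size Pixel size (nm).
#'
#' @return A list of `frame_stack` objects (ADU), one per plane.
#' @export
simulate_movie <- function(emitters, psf, geometry, cal, background,
                           n_frames, seed, pixel_size = 108) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cals <- if (inherits(cal, "camera_calibration")) {
    rep(list(cal), geometry$n_planes)
  } else {
    cal
  }
  bg <- rep(background, length.out = geometry$n_planes)
  shape <- cals[[1]]$shape
  with_seed(seed, {
    lapply(seq_len(geometry$n_planes), function(p) {
      arr <- array(0L, c(shape, n_frames))
      for (f in seq_len(n_frames) - 1L) {
        on <- if (nrow(emitters)) {
          vapply(emitters$on_frames, function(s) f %in% s, logical(1))
        } else {
          logical(0)
        }
        mu <- expected_plane_image(emitters[on, , drop = FALSE], psf,
                                   geometry, p, shape, bg[p], pixel_size)
        arr[, , f + 1L] <- render_adu(mu, cals[[p]])
      }
      frame_stack(arr, units = "adu", camera_id = sprintf("plane%d", p - 1L))
    })
  })
}

#' Simulate a bead z-stack calibration movie
#'
#' Emulates scanning beads fixed to a coverslip through the focal planes
#' with a piezo stage: at stage position `z` every bead is rendered at
#' axial position `z` in each plane (defocus `z - offset_p`). Bead
#' brightness is constant across the scan (no bleaching). Frames are
#' ordered by increasing stage z.
#'
#' @param beads Data frame with `x`, `y` (reference-frame pixels) and
#'   optionally `photons`.
#' @param psf,geometry,cal,seed,pixel_size As in [simulate_movie()].
#' @param z_range Length-2 scan range (nm); must cover all plane offsets.
#' @param z_step Scan step (nm), > 0.
#' @param frames_per_z Replicate frames per stage position.
#' @param background Background (e-/pixel).
#' @param photons Bead brightness (e-/frame) when `beads` has no
#'   `photons` column.
#'
#' @return List with `stacks` (one `frame_stack` per plane) and
#'   `schedule` (tibble `frame`, `z`).
#' @export
simulate_bead_zstack <- function(beads, psf, geometry, cal, z_range, z_step,
                                 frames_per_z = 1, seed, background = 5,
                                 photons = 20000, pixel_size = 108) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(z_step > 0)
  if (z_range[1] > min(geometry$focal_offsets) ||
      z_range[2] < max(geometry$focal_offsets)) {
    stop("configuration error: z_range must cover all plane offsets",
         call. = FALSE)
  }
  zs <- seq(z_range[1], z_range[2], by = z_step)
  if (!"photons" %in% names(beads)) beads$photons <- photons
  cals <- if (inherits(cal, "camera_calibration")) {
    rep(list(cal), geometry$n_planes)
  } else {
    cal
  }
  shape <- cals[[1]]$shape
  total <- length(zs) * frames_per_z
  schedule <- tibble::tibble(frame = seq_len(total) - 1L,
                             z = rep(zs, each = frames_per_z))
  stacks <- with_seed(seed, {
    lapply(seq_len(geometry$n_planes), function(p) {
      arr <- array(0L, c(shape, total))
      for (i in seq_len(total)) {
        em <- tibble::tibble(x = beads$x, y = beads$y, z = schedule$z[i],
                             photons = beads$photons)
        mu <- expected_plane_image(em, psf, geometry, p, shape,
                                   background, pixel_size)
        arr[, , i] <- render_adu(mu, cals[[p]])
      }
      frame_stack(arr, units = "adu", camera_id = sprintf("plane%d", p - 1L))
    })
  })
  list(stacks = stacks, schedule = schedule)
}

#' Collapse a bead z-stack to one averaged slice per stage position
#'
#' @param stack A corrected `frame_stack` (or array) from a z scan.
#' @param frames_per_z Replicates per stage position.
#' @return Array `[y, x, z]`.
#' @export
collapse_zstack <- function(stack, frames_per_z) {
  arr <- if (inherits(stack, "frame_stack")) stack$pixels else stack
  nz <- dim(arr)[3] / frames_per_z
  stopifnot(nz == round(nz))
  out <- array(0, c(dim(arr)[1:2], nz))
  for (i in seq_len(nz)) {
    idx <- ((i - 1L) * frames_per_z + 1L):(i * frames_per_z)
    out[, , i] <- apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
  }
  out
}

#' Dye spectral signatures and simulated spectral localizations
#'
#' A dye signature is the expected fraction of a localization's signal in
#' each of the 4 color channels. `simulate_spectral_localizations()` draws
#' a Poisson photon budget per localization and splits it multinomially
#' over channels — the physically consistent model of one emission stream
#' passing through sequential dichroics.
#'
#' @param fractions Non-negative 4-vector summing to 1.
#' @return `dye_signature()` returns a validated numeric 4-vector.
#' @export
dye_signature <- function(fractions) {
  if (length(fractions) != 4L || any(fractions < 0)) {
    stop("configuration error: signature must be 4 non-negative fractions",
         call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("configuration error: signature fractions must sum to 1",
         call. = FALSE)
  }
  as.numeric(fractions)
}

#' @rdname dye_signature
#' @param signatures List of signatures (one per dye).
#' @param n_per_dye Localizations per dye.
#' @param mean_photons Mean photon budget per localization (e-).
#' @param seed RNG seed (mandatory).
#' @return A tibble with `dye` (true label), and `signal_1..signal_4`.
#' @export
simulate_spectral_localizations <- function(signatures, n_per_dye,
                                            mean_photons = 4000, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  signatures <- lapply(signatures, dye_signature)
  with_seed(seed, {
    out <- lapply(seq_along(signatures), function(d) {
      n <- stats::rpois(n_per_dye, mean_photons)
      sig <- vapply(n, function(ni) {
        drop(stats::rmultinom(1, ni, signatures[[d]]))
      }, numeric(4))
      tibble::tibble(dye = d, signal_1 = sig[1, ], signal_2 = sig[2, ],
                     signal_3 = sig[3, ], signal_4 = sig[4, ])
    })
    dplyr::bind_rows(out)
  })
}
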