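#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types; `tidy()`/`glance()` return tibble summaries in the broom style.
#'
#' @name mvsmlm-plots
NULL

#' @describeIn mvsmlm-plots Rendered super-resolution image of a
#'   localization table.
#' @param object Object to plot/summarise.
#' @param bin_size_nm Render bin size (nm).
#' @param ... Unused.
#' @export
autoplot.localization_table <- function(object, bin_size_nm = 20, ...) {
  img <- render(object, bin_size_nm)
  df <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$counts <- c(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("x (%g nm bins)", bin_size_nm),
                  y = sprintf("y (%g nm bins)", bin_size_nm),
                  fill = "counts") +
    ggplot2::theme_minimal()
}

#' @describeIn mvsmlm-plots Drift trace (dx, dy, dz vs frame).
#' @param drift Drift tibble from [drift_correct()].
#' @export
plot_drift <- function(drift) {
  long <- tidyr_pivot(drift)
  ggplot2::ggplot(long, ggplot2::aes(.data$frame_mid, .data$offset,
                                     colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frame", y = "offset (nm)", colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(drift) {
  do.call(rbind, lapply(c("dx", "dy", "dz"), function(ax) {
    data.frame(frame_mid = drift$frame_mid, axis = ax,
               offset = drift[[ax]])
  }))
}

#' @describeIn mvsmlm-plots Spectral 4-vectors coloured by assigned label.
#' @param vectors Output of [channel_vector()].
#' @param labels Assigned labels (e.g. from [classify()]).
#' @export
plot_spectra <- function(vectors, labels = NULL) {
  df <- as.data.frame(vectors)
  df$moment <- first_moment(vectors)
  df$label <- if (is.null(labels)) "all" else factor(labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$moment, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "first spectral moment", y = "localizations") +
    ggplot2::theme_minimal()
}

#' @describeIn mvsmlm-plots One-row tibble of a CRB result.
#' @param x A `crb_result`.
#' @export
tidy.crb_result <- function(x, ...) {
  tibble::tibble(term = c("sigma_x", "sigma_y", "sigma_z"),
                 estimate = c(x$sigma_x, x$sigma_y, x$sigma_z),
                 method = x$method)
}

#' @describeIn mvsmlm-plots One-row model summary of a cluster model.
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, seed = x$seed)
}

#' @describeIn mvsmlm-plots Localization-table summary: counts by status,
#'   mean photons/background.
#' @export
glance.localization_table <- function(x, ...) {
  conv <- x$status == "converged"
  tibble::tibble(
    n = nrow(x),
    n_converged = sum(conv),
    mean_photons = mean(x$photons[conv]),
    mean_background = mean(x$background[conv]),
    n_frames = attr(x, "n_frames"),
    pixel_size = attr(x, "pixel_size"))
}
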