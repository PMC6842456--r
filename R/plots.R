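#' Density plot of diel displacement rates by starting anchor
#'
#' @param disp A [compute_displacements()] table.
#' @return A ggplot.
#' @export
plot_displacement_density <- function(disp) {
  ggplot2::ggplot(disp, ggplot2::aes(x = .data$rate_m_per_h,
                                     colour = .data$start_anchor)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "displacement rate (m/h)", y = "density",
                  colour = "anchor",
                  title = sprintf("%g-h displacement by diel anchor",
                                  disp$nominal_lag_h[1])) +
    ggplot2::theme_minimal()
}

#' Tile map of a time-use grid statistic
#'
#' @param grid A `time_use_grid` or `biweekly_timeuse`.
#' @param stat `"nsv"` or `"mlsv"`.
#' @return A ggplot (faceted by individual when several are present).
#' @export
plot_timeuse_grid <- function(grid, stat = c("nsv", "mlsv")) {
  stat <- match.arg(stat)
  cells <- grid$cells
  sp <- grid$spec
  p <- ggplot2::ggplot(cells, ggplot2::aes(
    x = sp$origin_x + (.data$col + 0.5) * sp$cell_size,
    y = sp$origin_y + (.data$row + 0.5) * sp$cell_size,
    fill = .data[[stat]]
  )) +
    ggplot2::geom_tile(width = sp$cell_size, height = sp$cell_size) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)", fill = stat) +
    ggplot2::theme_minimal()
  if (length(unique(cells$individual_id)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$individual_id))
  }
  p
}

#' @export
autoplot.time_use_grid <- function(object, stat = "nsv", ...) {
  plot_timeuse_grid(object, stat)
}

#' @export
autoplot.biweekly_timeuse <- function(object, stat = "nsv", ...) {
  plot_timeuse_grid(object, stat)
}

#' Histogram of annual time-to-return, 7-day bins
#'
#' @param returns A [return_times()] table.
#' @param bin_days Bin width (default 7 days).
#' @return A ggplot, faceted by individual.
#' @export
plot_return_histogram <- function(returns, bin_days = 7) {
  ggplot2::ggplot(returns, ggplot2::aes(x = .data$gap_days,
                                        fill = factor(.data$cell_nsv))) +
    ggplot2::geom_histogram(binwidth = bin_days, boundary = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$individual_id)) +
    ggplot2::labs(x = "days to return", y = "returns", fill = "cell nsv") +
    ggplot2::theme_minimal()
}

#' Heat map of revisitation against greenness
#'
#' The binned density emitted by [recursion_vs_ndvi()] (revisited cells
#' only, nsv >= 2), with a log-transformed count scale so structure at low
#' nsv stays visible.
#'
#' @param comparison An `ndvi_model_comparison`.
#' @return A ggplot.
#' @export
plot_nsv_greenness <- function(comparison) {
  ggplot2::ggplot(comparison$density,
                  ggplot2::aes(x = .data$greenness_bin, y = .data$nsv,
                               fill = .data$n_cells)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "mean greenness (binned)", y = "nsv",
                  fill = "cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.ndvi_model_comparison <- function(object, ...) {
  plot_nsv_greenness(object)
}

#' @export
autoplot.home_range_isopleth <- function(object, ...) {
  rings <- purrr::imap_dfr(object$polygon, function(r, i) {
    tibble::tibble(hull = i, x = r[, 1], y = r[, 2])
  })
  ggplot2::ggplot(rings, ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$hull)) +
    ggplot2::geom_polygon(fill = "forestgreen", alpha = 0.3,
                          colour = "darkgreen", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "easting (m)", y = "northing (m)",
      title = sprintf("%g%% k-LoCoH isopleth (k = %d, %.2f km^2)",
                      100 * object$level, object$k_used,
                      object$area_m2 / 1e6)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
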