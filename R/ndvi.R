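#' Per-cell greenness statistics from a raster
#'
#' Summarises, for each requested grid cell, the unmasked raster pixels whose
#' centres fall inside the cell (no area weighting: 250 m pixels nest ~16:1
#' in 1 km cells, so partial-pixel weighting is immaterial and the rule is
#' deterministic). Cells containing no unmasked pixel centre are dropped with
#' a warning. The standard deviation uses the n-1 denominator.
#'
#' @param cells Tibble with `col`, `row` (0-based cell indices); typically
#'   the `cells` table of a [build_time_use_grid()] or [biweekly_time_use()].
#' @param spec The [grid_spec()] the indices refer to.
#' @param raster A [greenness_raster()].
#' @return `cells` with `ndvi_mean`, `ndvi_median`, `ndvi_min`, `ndvi_max`,
#'   `ndvi_sd`, `n_pixels` appended (pixel-empty cells removed).
#' @export
extract_cell_stats <- function(cells, spec, raster) {
  px <- raster_pixel_centres(raster)
  px <- assign_cells(dplyr::rename(px, x = "px", y = "py"), spec)
  stats_tbl <- px |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(ndvi_mean = mean(.data$value),
                     ndvi_median = stats::median(.data$value),
                     ndvi_min = min(.data$value),
                     ndvi_max = max(.data$value),
                     ndvi_sd = stats::sd(.data$value),
                     n_pixels = dplyr::n(), .groups = "drop")
  if (!"cell_id" %in% names(cells)) {
    cells <- dplyr::mutate(cells, cell_id = paste0(.data$col, "_", .data$row))
  }
  out <- dplyr::inner_join(cells, stats_tbl, by = "cell_id")
  dropped <- nrow(cells) - nrow(out)
  if (dropped > 0) {
    warning(dropped, " cell(s) without unmasked pixel centres dropped")
  }
  out
}

#' Join biweekly time-use cells to contemporaneous greenness rasters
#'
#' Each qualifying interval's cells are joined to the raster whose
#' compositing period starts on the interval's start date.
#'
#' @param timeuse A [biweekly_time_use()] result.
#' @param rasters List of [greenness_raster()] with `period_start` set.
#' @return Long tibble of cells with greenness statistics appended.
#' @export
join_cells_greenness <- function(timeuse, rasters) {
  starts <- as.Date(vapply(rasters, function(r) as.character(r$period_start),
                           character(1)))
  timeuse$cells |>
    dplyr::group_by(.data$interval_start) |>
    dplyr::group_modify(function(d, key) {
      i <- match(key$interval_start, starts)
      if (is.na(i)) stop("no raster for compositing period starting ",
                         key$interval_start)
      extract_cell_stats(d, timeuse$spec, rasters[[i]])
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("individual_id")
}

#' Characterise the recursion-greenness relationship
#'
#' Fits `nsv ~ greenness` (linear) and `nsv ~ greenness + greenness^2`
#' (quadratic) by least squares on the joined cell table and compares them by
#' AIC; a hill-shaped relationship (revisitation peaking at mid-range
#' greenness) prefers the quadratic with a negative curvature, whose implied
#' optimum `-b1/(2*b2)` is reported. A 2-D binned density table
#' (nsv x mean greenness) restricted to revisited cells (nsv >= 2) is
#' emitted for plotting.
#'
#' @param joined Output of [join_cells_greenness()] (needs `nsv`,
#'   `ndvi_mean`).
#' @param min_rows Minimum joined rows to attempt the fits.
#' @param greenness_breaks Bin edges for the density table.
#' @return A list of class `ndvi_model_comparison`: `linear_fit`,
#'   `quadratic_fit` (lm objects), `aic_linear`, `aic_quadratic`,
#'   `preferred`, `optimum` (NA when the quadratic opens upward), `n`,
#'   `density` (tibble nsv x greenness bin counts).
#' @export
recursion_vs_ndvi <- function(joined, min_rows = 30,
                              greenness_breaks = seq(-1, 1, by = 0.025)) {
  if (nrow(joined) < min_rows) {
    stop("insufficient data: ", nrow(joined), " joined rows (need >= ",
         min_rows, ")")
  }
  if (stats::sd(joined$ndvi_mean) == 0) stop("degenerate greenness variance")
  lin <- stats::lm(nsv ~ ndvi_mean, data = joined)
  quad <- stats::lm(nsv ~ ndvi_mean + I(ndvi_mean^2), data = joined)
  aic_l <- stats::AIC(lin); aic_q <- stats::AIC(quad)
  b <- stats::coef(quad)
  optimum <- if (b[3] < 0) unname(-b[2] / (2 * b[3])) else NA_real_
  dens <- joined |>
    dplyr::filter(.data$nsv >= 2) |>
    dplyr::mutate(greenness_bin = cut(.data$ndvi_mean, greenness_breaks,
                                      include.lowest = TRUE)) |>
    dplyr::count(.data$nsv, .data$greenness_bin, name = "n_cells")
  structure(list(linear_fit = lin, quadratic_fit = quad,
                 aic_linear = aic_l, aic_quadratic = aic_q,
                 preferred = if (aic_q < aic_l) "quadratic" else "linear",
                 optimum = optimum, n = nrow(joined), density = dens),
            class = "ndvi_model_comparison")
}

#' @export
print.ndvi_model_comparison <- function(x, ...) {
  cat(sprintf("nsv ~ greenness model comparison (n = %d cells)\n", x$n))
  cat(sprintf("  linear AIC %.1f, quadratic AIC %.1f -> %s preferred\n",
              x$aic_linear, x$aic_quadratic, x$preferred))
  if (!is.na(x$optimum)) {
    cat(sprintf("  quadratic optimum at greenness %.3f\n", x$optimum))
  }
  invisible(x)
}

#' @export
tidy.ndvi_model_comparison <- function(x, ...) {
  cl <- stats::coef(x$linear_fit); cq <- stats::coef(x$quadratic_fit)
  tibble::tibble(
    model = c(rep("linear", length(cl)), rep("quadratic", length(cq))),
    term = c(names(cl), names(cq)),
    estimate = c(unname(cl), unname(cq))
  )
}

#' @export
glance.ndvi_model_comparison <- function(x, ...) {
  tibble::tibble(aic_linear = x$aic_linear, aic_quadratic = x$aic_quadratic,
                 preferred = x$preferred, optimum = x$optimum, n = x$n)
}
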