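#' Annual-scale visits at a 7-day inter-visit gap
#'
#' Builds a time-use grid over each individual's full trajectory with a
#' 7-day inter-visit gap, the scale at which returns to a cell reflect
#' returns after genuinely leaving the area rather than daily shuttling.
#' Individuals whose trajectory spans fewer than `min_span_days` are flagged
#' with a warning (or dropped when `require_span`), since short records bias
#' annual recursion low.
#'
#' @param fixes A fix tibble.
#' @param spec Optional [grid_spec()]; defaults to 1 km cells snapped to the
#'   fixes.
#' @param ivg_days Inter-visit gap in days (default 7).
#' @param min_span_days Minimum span for an individual to be considered
#'   annual (default 300).
#' @param require_span Drop (rather than warn about) short individuals.
#' @return A `time_use_grid` (see [build_time_use_grid()]).
#' @export
annual_visits <- function(fixes, spec = NULL, ivg_days = 7,
                          min_span_days = 300, require_span = FALSE) {
  spans <- fixes |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(span = as.numeric(difftime(max(.data$t), min(.data$t),
                                                units = "days")),
                     .groups = "drop")
  short <- spans$individual_id[spans$span < min_span_days]
  if (length(short) > 0) {
    warning("trajectory span under ", min_span_days, " days for: ",
            paste(short, collapse = ", "))
    if (require_span) {
      fixes <- dplyr::filter(fixes, !.data$individual_id %in% short)
      if (nrow(fixes) == 0) stop("no individual meets the span requirement")
    }
  }
  build_time_use_grid(fixes, spec, ivg_hours = ivg_days * 24)
}

#' Flag and exclude grid cells containing a waterhole
#'
#' A cell is a waterhole cell when at least one waterhole point falls inside
#' its half-open square. Waterhole cells are excluded from the return-time
#' analysis (so recursion to presumed foraging sites is measured
#' independently of drinking) but remain, flagged, in the grid for range
#' metrics, where their often very high visitation is still of interest.
#'
#' @param grid A `time_use_grid`.
#' @param waterholes Tibble with waterhole `x`, `y`.
#' @return The grid with a logical `waterhole` column added to `cells` and
#'   `visits`.
#' @export
exclude_waterhole_cells <- function(grid, waterholes) {
  wh_cells <- if (nrow(waterholes) == 0) character(0) else
    unique(assign_cells(waterholes, grid$spec)$cell_id)
  grid$cells <- dplyr::mutate(grid$cells,
                              waterhole = .data$cell_id %in% wh_cells)
  grid$visits <- dplyr::mutate(grid$visits,
                               waterhole = .data$cell_id %in% wh_cells)
  grid
}

#' Time-to-return table for frequently revisited cells
#'
#' For every cell with at least `min_visits` separate visits (and not
#' flagged as a waterhole cell), reports the gap in days between the end of
#' each visit and the start of the next, i.e. the time away before
#' returning.
#'
#' @param grid A `time_use_grid`, typically from [annual_visits()] and
#'   [exclude_waterhole_cells()].
#' @param min_visits Minimum visits for a cell to qualify (default 3).
#' @return Tibble with `individual_id`, `cell_id`, `gap_days`, `cell_nsv`.
#' @export
return_times <- function(grid, min_visits = 3) {
  visits <- grid$visits
  if ("waterhole" %in% names(visits)) {
    visits <- dplyr::filter(visits, !.data$waterhole)
  }
  visits |>
    dplyr::group_by(.data$individual_id, .data$cell_id) |>
    dplyr::filter(dplyr::n() >= min_visits) |>
    dplyr::arrange(.data$first_t, .by_group = TRUE) |>
    dplyr::reframe(
      gap_days = as.numeric(difftime(.data$first_t[-1],
                                     .data$last_t[-dplyr::n()],
                                     units = "days")),
      cell_nsv = dplyr::n()
    )
}

#' Bin return times into fixed-width histogram counts
#'
#' @param returns A [return_times()] table.
#' @param bin_days Bin width in days (default 7).
#' @return Tibble with `bin` (1-based index), `bin_start_days`,
#'   `bin_end_days`, `n_returns`.
#' @export
bin_return_times <- function(returns, bin_days = 7) {
  if (nrow(returns) == 0) {
    return(tibble::tibble(bin = integer(), bin_start_days = numeric(),
                          bin_end_days = numeric(), n_returns = integer()))
  }
  bin <- pmax(1L, as.integer(ceiling(returns$gap_days / bin_days)))
  tibble::tibble(bin = bin) |>
    dplyr::count(.data$bin, name = "n_returns") |>
    dplyr::mutate(bin_start_days = (.data$bin - 1) * bin_days,
                  bin_end_days = .data$bin * bin_days) |>
    dplyr::relocate("bin", "bin_start_days", "bin_end_days")
}

#' Per-individual range and revisitation metrics
#'
#' Range size is the number of grid cells visited at least once; the mean,
#' median and SD of nsv are taken over cells with at least two visits; the
#' proportion revisited divides cells with >= 2 visits by cells with
#' >= 1 visit; the top-quartile count is the number of cells whose nsv is at
#' least the individual's 75th percentile of nsv over all visited cells
#' (linear-interpolation quantile; ties included).
#'
#' @param grid A `time_use_grid` (annual scale).
#' @return Tibble with one row per individual: `individual_id`,
#'   `range_size`, `mean_nsv`, `median_nsv`, `sd_nsv`, `prop_revisited`,
#'   `top_quartile_count`.
#' @export
range_metrics <- function(grid) {
  cells <- grid$cells
  if (nrow(cells) == 0) stop("no visited cells")
  cells |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      range_size = dplyr::n(),
      mean_nsv = mean_or_na(.data$nsv[.data$nsv >= 2]),
      median_nsv = median_or_na(.data$nsv[.data$nsv >= 2]),
      sd_nsv = sd_or_na(.data$nsv[.data$nsv >= 2]),
      prop_revisited = sum(.data$nsv >= 2) / dplyr::n(),
      top_quartile_count = sum(.data$nsv >=
                                 stats::quantile(.data$nsv, 0.75, type = 7)),
      .groups = "drop"
    )
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
median_or_na <- function(x) if (length(x) == 0) NA_real_ else stats::median(x)
sd_or_na <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

#' Correlations between range size and revisitation metrics
#'
#' Pearson correlations (with Fisher-z CIs) of range size against median
#' nsv, SD of nsv, and proportion of cells revisited; optionally recomputed
#' with one individual left out, as a sensitivity check against a single
#' outlier.
#'
#' @param metrics A [range_metrics()] table (>= 4 individuals).
#' @param leave_out Optional individual_id to drop for a sensitivity rerun.
#' @return Tibble with `metric`, `estimate`, `p.value`, `conf.low`,
#'   `conf.high`, `n`, `excluded`.
#' @export
range_correlations <- function(metrics, leave_out = NULL) {
  one_set <- function(m, tag) {
    if (nrow(m) < 4) stop("need at least 4 individuals")
    purrr::map_dfr(
      c(median_nsv = "median_nsv", sd_nsv = "sd_nsv",
        prop_revisited = "prop_revisited"),
      function(col) tidy(pearson_ci(m$range_size, m[[col]])),
      .id = "metric"
    ) |>
      dplyr::mutate(excluded = tag)
  }
  out <- one_set(metrics, "none")
  if (!is.null(leave_out)) {
    out <- dplyr::bind_rows(
      out,
      one_set(dplyr::filter(metrics, .data$individual_id != leave_out),
              leave_out)
    )
  }
  out
}
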