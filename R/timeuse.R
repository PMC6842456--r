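#' Start dates of 16-day compositing periods covering a date range
#'
#' Compositing periods restart on day-of-year 1 of each calendar year and run
#' 1, 17, 33, ..., 337, 353; the final (23rd) period of a year is truncated
#' at the year boundary and is excluded, leaving 22 full 16-day windows per
#' year.
#'
#' @param from,to Dates bounding the range (inclusive).
#' @return A `Date` vector of period starts whose window overlaps the range.
#' @export
compositing_starts <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  years <- seq(as.integer(format(from, "%Y")), as.integer(format(to, "%Y")))
  starts <- as.Date(unlist(lapply(years, function(y) {
    as.character(as.Date(sprintf("%d-01-01", y)) + 16 * (0:21))
  })))
  starts[starts + 15 >= from & starts <= to]
}

#' Assign fixes to 16-day compositing intervals
#'
#' Each fix is assigned by its local calendar date to the half-open 16-day
#' window `[start, start + 16 d)` of the compositing calendar
#' ([compositing_starts()]). Fixes falling in a year's truncated final window
#' (local day-of-year 353 onward) get `NA` and take no part in biweekly
#' analyses.
#'
#' @param fixes A fix tibble.
#' @param utc_offset Hours added to UTC to obtain local clock time.
#' @return `fixes` with `local_date` and `interval_start` (Date) appended.
#' @export
segment_intervals <- function(fixes, utc_offset = 2) {
  local_date <- as.Date(fixes$t + utc_offset * 3600, tz = "UTC")
  doy <- as.integer(format(local_date, "%j"))
  win <- (doy - 1L) %/% 16L
  year_start <- as.Date(paste0(format(local_date, "%Y"), "-01-01"))
  interval_start <- year_start + 16L * win
  interval_start[win >= 22L] <- NA
  dplyr::mutate(fixes, local_date = local_date,
                interval_start = interval_start)
}

#' Daily-coverage summary and filter for 16-day intervals
#'
#' An interval of an individual's trajectory qualifies for biweekly analysis
#' when at least `min_days` distinct local calendar dates of the window carry
#' at least one fix (days are counted, not fixes), screening out windows with
#' large gaps.
#'
#' @param fixes A fix tibble already passed through [segment_intervals()] (it
#'   is called internally when the columns are absent).
#' @param min_days Minimum distinct fix-days (default 15 of 16).
#' @param utc_offset Hours added to UTC for local dates.
#' @return A tibble with `individual_id`, `interval_start`, `days_with_fix`,
#'   `n_fixes`, `pass` (logical).
#' @export
interval_coverage <- function(fixes, min_days = 15, utc_offset = 2) {
  if (!all(c("local_date", "interval_start") %in% names(fixes))) {
    fixes <- segment_intervals(fixes, utc_offset)
  }
  fixes |>
    dplyr::filter(!is.na(.data$interval_start)) |>
    dplyr::group_by(.data$individual_id, .data$interval_start) |>
    dplyr::summarise(days_with_fix = dplyr::n_distinct(.data$local_date),
                     n_fixes = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(pass = .data$days_with_fix >= min_days)
}

#' Build a time-use grid (visits, nsv, mlsv) from fixes
#'
#' Assigns each fix to a grid cell and splits each cell's in-cell fix
#' sequence into separate visits wherever the gap between successive in-cell
#' fixes exceeds the inter-visit gap `ivg` (strictly; a gap of exactly `ivg`
#' does not split). Excursions to other cells between two in-cell fixes less
#' than `ivg` apart do not end a visit. Per cell the grid carries the number
#' of separate visits (nsv, a recursion measure) and the mean locations per
#' separate visit (mlsv, a visit-duration measure).
#'
#' @param fixes A fix tibble (may contain several individuals; visits are
#'   built per individual).
#' @param spec A [grid_spec()]; defaults to [snap_grid()] of the fixes at
#'   1 km cells.
#' @param ivg_hours Inter-visit gap in hours (12 for the biweekly analysis,
#'   168 = 7 days for the annual analysis).
#' @return A list of class `time_use_grid`: `spec`, `ivg_hours`, `visits`
#'   (tibble: individual_id, cell_id, col, row, visit, first_t, last_t,
#'   n_locations) and `cells` (tibble: individual_id, cell_id, col, row,
#'   n_fixes, nsv, mlsv).
#' @examples
#' fx <- tibble::tibble(individual_id = "A",
#'                      t = as.POSIXct("2012-01-01", tz = "UTC") +
#'                        c(0, 1, 14) * 3600,
#'                      x = 100, y = 100)
#' build_time_use_grid(fx, ivg_hours = 12)$cells
#' @export
build_time_use_grid <- function(fixes, spec = NULL, ivg_hours = 12) {
  if (ivg_hours <= 0) stop("ivg must be positive")
  if (is.null(spec)) spec <- snap_grid(fixes)
  pts <- assign_cells(fixes, spec) |>
    dplyr::arrange(.data$individual_id, .data$t)
  visits <- pts |>
    dplyr::group_by(.data$individual_id, .data$cell_id, .data$col, .data$row) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(gap_h = as.numeric(difftime(.data$t, dplyr::lag(.data$t),
                                              units = "hours")),
                  visit = cumsum(is.na(.data$gap_h) | .data$gap_h > ivg_hours)) |>
    dplyr::group_by(.data$visit, .add = TRUE) |>
    dplyr::summarise(first_t = min(.data$t), last_t = max(.data$t),
                     n_locations = dplyr::n(), .groups = "drop")
  cells <- visits |>
    dplyr::group_by(.data$individual_id, .data$cell_id, .data$col, .data$row) |>
    dplyr::summarise(n_fixes = sum(.data$n_locations),
                     nsv = dplyr::n(),
                     mlsv = sum(.data$n_locations) / dplyr::n(),
                     .groups = "drop")
  structure(list(spec = spec, ivg_hours = ivg_hours,
                 visits = visits, cells = cells),
            class = "time_use_grid")
}

#' @export
print.time_use_grid <- function(x, ...) {
  cat(sprintf("<time_use_grid> ivg %g h, %d visited cells, %d visits\n",
              x$ivg_hours, nrow(x$cells), nrow(x$visits)))
  invisible(x)
}

#' Biweekly time-use statistics across all qualifying 16-day intervals
#'
#' Segments trajectories into 16-day compositing intervals, applies the
#' daily-coverage filter, and builds a time-use grid per individual and
#' interval on a common 1 km grid, returning one long table of per-cell
#' statistics ready for the greenness join.
#'
#' @inheritParams build_time_use_grid
#' @inheritParams interval_coverage
#' @param cell_size Cell edge in metres.
#' @return A list of class `biweekly_timeuse`: `spec`, `ivg_hours`, `cells`
#'   (tibble with individual_id, interval_start, cell_id, col, row, n_fixes,
#'   nsv, mlsv) and `coverage` (the [interval_coverage()] table).
#' @export
biweekly_time_use <- function(fixes, cell_size = 1000, ivg_hours = 12,
                              min_days = 15, utc_offset = 2) {
  seg <- segment_intervals(fixes, utc_offset)
  cov <- interval_coverage(seg, min_days = min_days)
  keep <- dplyr::semi_join(
    dplyr::filter(seg, !is.na(.data$interval_start)),
    dplyr::filter(cov, .data$pass),
    by = c("individual_id", "interval_start")
  )
  spec <- snap_grid(fixes, cell_size)
  if (nrow(keep) == 0) {
    warning("no interval passes the coverage filter")
    cells <- tibble::tibble(individual_id = character(),
                            interval_start = as.Date(character()),
                            cell_id = character(), col = integer(),
                            row = integer(), n_fixes = integer(),
                            nsv = integer(), mlsv = numeric())
  } else {
    cells <- keep |>
      dplyr::group_by(.data$interval_start) |>
      dplyr::group_modify(function(d, key) {
        build_time_use_grid(d, spec, ivg_hours)$cells
      }) |>
      dplyr::ungroup() |>
      dplyr::relocate("individual_id")
  }
  structure(list(spec = spec, ivg_hours = ivg_hours, cells = cells,
                 coverage = cov),
            class = "biweekly_timeuse")
}

#' @export
print.biweekly_timeuse <- function(x, ...) {
  cat(sprintf("<biweekly_timeuse> %d interval-cells over %d qualifying intervals (ivg %g h)\n",
              nrow(x$cells), sum(x$coverage$pass), x$ivg_hours))
  invisible(x)
}
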