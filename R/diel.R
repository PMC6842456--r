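#' Diel anchor configuration
#'
#' Four local clock times anchor the diel cycle: dawn 07:00, midday 13:00,
#' dusk 19:00 and midnight 01:00, each with a selection window of plus/minus
#' `tolerance_h` hours (default 2.5 h, wide enough to absorb seasonal
#' sunrise/sunset variation without an ephemeris). Timestamps are stored in
#' UTC; local clock time is UTC plus a fixed `utc_offset`.
#'
#' @param dawn,midday,dusk,midnight Local anchor hours (decimal hours 0-24).
#' @param tolerance_h Half-width of each anchor window in hours.
#' @param utc_offset Hours added to UTC to obtain local time (default +2).
#' @return A list of class `anchor_config`.
#' @export
anchor_config <- function(dawn = 7, midday = 13, dusk = 19, midnight = 1,
                          tolerance_h = 2.5, utc_offset = 2) {
  stopifnot(tolerance_h > 0)
  structure(list(anchors = c(dawn = dawn, midday = midday, dusk = dusk,
                             midnight = midnight),
                 tolerance_h = tolerance_h, utc_offset = utc_offset),
            class = "anchor_config")
}

# chronological position of each anchor within a calendar day
anchor_day_order <- function(cfg) {
  names(sort(cfg$anchors))
}

#' Standardise irregular fixes to one fix per diel anchor per day
#'
#' For each individual, local date and anchor, all fixes whose local time
#' falls within `tolerance_h` of the anchor instant are candidates; the one
#' minimising the absolute offset is selected (ties broken by the earlier
#' timestamp). An anchor whose window spans midnight (e.g. the 01:00 anchor)
#' assigns its fixes to the date of the anchor instant, not the fix's own
#' date. Days without a qualifying fix simply yield no record.
#'
#' @param fixes A fix tibble.
#' @param cfg An [anchor_config()].
#' @return A tibble with `individual_id`, `date` (local date of the anchor
#'   instant), `anchor` (factor dawn/midday/dusk/midnight), `t`, `x`, `y`,
#'   `sex`, `offset_min` (signed minutes from the anchor instant).
#' @examples
#' fx <- tibble::tibble(individual_id = "A",
#'                      t = as.POSIXct("2012-04-01 03:45", tz = "UTC"),
#'                      x = 0, y = 0, sex = "female")
#' standardize_diel_fixes(fx, anchor_config())  # 05:45 local -> dawn fix
#' @export
standardize_diel_fixes <- function(fixes, cfg = anchor_config()) {
  if (nrow(fixes) == 0) {
    return(tibble::tibble(individual_id = character(),
                          date = as.Date(character()), anchor = character(),
                          t = as.POSIXct(character(), tz = "UTC"),
                          x = numeric(), y = numeric(), sex = character(),
                          offset_min = numeric()))
  }
  local_t <- fixes$t + cfg$utc_offset * 3600
  local_date <- as.Date(local_t, tz = "UTC")
  secs_of_day <- as.numeric(difftime(local_t,
                                     as.POSIXct(paste(local_date, "00:00:00"),
                                                tz = "UTC"),
                                     units = "secs"))
  tol_s <- cfg$tolerance_h * 3600
  per_anchor <- lapply(names(cfg$anchors), function(a) {
    anchor_s <- cfg$anchors[[a]] * 3600
    # offset to the anchor instant of the fix's own date, and of the
    # neighbouring dates, so windows spanning midnight are honoured
    best <- NULL
    for (shift in -1:1) {
      off <- secs_of_day - (anchor_s + shift * 86400)
      cand <- abs(off) <= tol_s
      if (!any(cand)) next
      d <- tibble::tibble(
        individual_id = fixes$individual_id[cand],
        date = local_date[cand] + shift,
        anchor = a,
        t = fixes$t[cand], x = fixes$x[cand], y = fixes$y[cand],
        sex = if ("sex" %in% names(fixes)) fixes$sex[cand] else "unknown",
        offset_min = off[cand] / 60
      )
      best <- if (is.null(best)) d else dplyr::bind_rows(best, d)
    }
    best
  })
  out <- dplyr::bind_rows(per_anchor)
  if (nrow(out) == 0) return(out)
  out |>
    dplyr::group_by(.data$individual_id, .data$date, .data$anchor) |>
    dplyr::arrange(abs(.data$offset_min), .data$t, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$individual_id, .data$t)
}

#' Classify a timestamp into the wet or dry season
#'
#' Wet season is November-March, dry season April-October, by the local
#' calendar month (rainfall-defined seasons for the north-Namibian study
#' system).
#'
#' @param t POSIXct timestamps (UTC).
#' @param utc_offset Hours added to UTC for the local month.
#' @return Character vector, `"wet"` or `"dry"`.
#' @export
classify_season <- function(t, utc_offset = 2) {
  m <- as.integer(format(t + utc_offset * 3600, "%m", tz = "UTC"))
  ifelse(m %in% c(11, 12, 1, 2, 3), "wet", "dry")
}

#' Time-standardised displacements between diel fixes
#'
#' Pairs diel-standardised fixes a nominal 6, 12 or 24 hours apart and
#' reports the straight-line displacement divided by the exact elapsed time
#' (m/h), so irregular true fix times do not bias the comparison. Anchor
#' slots follow the chronological cycle midnight - dawn - midday - dusk: a
#' 24-h record pairs the same anchor on consecutive days, a 12-h record pairs
#' anchors two slots apart (e.g. dawn to dusk), a 6-h record pairs adjacent
#' slots. A fix may end one record and start the next.
#'
#' @param diel Output of [standardize_diel_fixes()].
#' @param lag_hours Nominal lag: 6, 12 or 24.
#' @param cfg The [anchor_config()] used (for the season's local offset and
#'   the elapsed-time sanity window).
#' @return A tibble with one row per displacement record: individual, start
#'   and end anchor, timestamps, `distance_m`, `elapsed_h`, `rate_m_per_h`,
#'   `nominal_lag_h`, `season` (of the start fix) and `sex`.
#' @export
compute_displacements <- function(diel, lag_hours = 24, cfg = anchor_config()) {
  if (!lag_hours %in% c(6, 12, 24)) stop("lag_hours must be 6, 12 or 24")
  ord <- anchor_day_order(cfg)
  steps <- lag_hours / 6
  if (nrow(diel) == 0) return(empty_displacements())
  d <- diel |>
    dplyr::mutate(slot = as.numeric(.data$date) * 4 +
                    match(.data$anchor, ord) - 1) |>
    dplyr::arrange(.data$individual_id, .data$slot)
  out <- d |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(function(g, key) {
      i <- match(g$slot + steps, g$slot)
      ok <- !is.na(i)
      j <- i[ok]
      s <- which(ok)
      elapsed <- as.numeric(difftime(g$t[j], g$t[s], units = "hours"))
      tibble::tibble(
        start_anchor = g$anchor[s], end_anchor = g$anchor[j],
        start_t = g$t[s], end_t = g$t[j],
        distance_m = sqrt((g$x[j] - g$x[s])^2 + (g$y[j] - g$y[s])^2),
        elapsed_h = elapsed,
        sex = g$sex[s]
      )
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::filter(.data$elapsed_h > 0,
                  abs(.data$elapsed_h - lag_hours) <= 2 * cfg$tolerance_h) |>
    dplyr::mutate(rate_m_per_h = .data$distance_m / .data$elapsed_h,
                  nominal_lag_h = lag_hours,
                  season = classify_season(.data$start_t, cfg$utc_offset))
}

empty_displacements <- function() {
  tibble::tibble(individual_id = character(), start_anchor = character(),
                 end_anchor = character(),
                 start_t = as.POSIXct(character(), tz = "UTC"),
                 end_t = as.POSIXct(character(), tz = "UTC"),
                 distance_m = numeric(), elapsed_h = numeric(),
                 sex = character(), rate_m_per_h = numeric(),
                 nominal_lag_h = numeric(), season = character())
}

#' Waterhole-proximity counts per diel anchor
#'
#' Counts, per anchor, the diel fixes whose distance to the nearest waterhole
#' is at most `radius_m` (inclusive), with the proportion of that anchor's
#' fixes. Mirrors the question of which time of day finds animals near
#' standing water.
#'
#' @param diel Output of [standardize_diel_fixes()].
#' @param waterholes Tibble with waterhole `x`, `y`.
#' @param radius_m Proximity radius in metres (default 250).
#' @return Tibble with `anchor`, `n_fixes`, `n_near`, `prop_near`.
#' @export
waterhole_proximity_counts <- function(diel, waterholes, radius_m = 250) {
  if (nrow(waterholes) == 0) stop("empty waterhole set")
  if (radius_m <= 0) stop("radius must be positive")
  d2 <- outer(diel$x, waterholes$x, "-")^2 + outer(diel$y, waterholes$y, "-")^2
  near <- sqrt(apply(d2, 1, min)) <= radius_m
  diel |>
    dplyr::mutate(near = near) |>
    dplyr::group_by(.data$anchor) |>
    dplyr::summarise(n_fixes = dplyr::n(), n_near = sum(.data$near),
                     prop_near = mean(.data$near), .groups = "drop")
}
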