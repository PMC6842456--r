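#' k-LoCoH utilization-distribution isopleth
#'
#' Local-convex-hull home-range estimation: around every fix, the convex hull
#' of that fix and its k-1 nearest neighbours (Euclidean; distance ties
#' broken by timestamp order) is built; hulls are sorted by ascending area
#' (the classic LoCoH density proxy), ties by enclosed-fix count descending
#' then focal timestamp, and unioned cumulatively until the union covers at
#' least `level` of the fixes. The result is a conservative non-parametric
#' utilization-distribution isopleth that respects hard boundaries and
#' unused areas.
#'
#' @param fixes A fix tibble (a single individual's fixes; `t` used only for
#'   tie-breaking, which sorts the table by time first).
#' @param k Hull size (focal point plus k-1 neighbours, k >= 3); default
#'   `ceiling(sqrt(n))`, a common heuristic.
#' @param level Coverage level in (0, 1]; default 0.90.
#' @return A list of class `home_range_isopleth`: `polygon` (list of convex
#'   rings whose union is the isopleth), `area_m2`, `level`, `k_used`,
#'   `n_points_covered`, `n_total`, `n_hulls_used`, `degenerate` flag and
#'   `hulls` (tibble of all candidate hulls with their areas and enclosed
#'   counts, in union order).
#' @examples
#' fx <- tibble::tibble(individual_id = "A",
#'                      t = as.POSIXct("2012-01-01", tz = "UTC") + 0:3 * 3600,
#'                      x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
#' klocoh_isopleth(fx, k = 4)$area_m2  # 1 km^2 square
#' @export
klocoh_isopleth <- function(fixes, k = NULL, level = 0.90) {
  stopifnot(level > 0, level <= 1)
  fixes <- dplyr::arrange(fixes, .data$t)
  n <- nrow(fixes)
  if (is.null(k)) k <- max(3L, ceiling(sqrt(n)))
  if (k < 3) stop("k must be at least 3")
  if (n < k) stop("need at least k fixes (n = ", n, ", k = ", k, ")")
  pts <- cbind(fixes$x, fixes$y)
  if (all(pts[, 1] == pts[1, 1]) && all(pts[, 2] == pts[1, 2])) {
    return(structure(list(polygon = list(), area_m2 = 0, level = level,
                          k_used = k, n_points_covered = n, n_total = n,
                          n_hulls_used = 0L, degenerate = TRUE,
                          hulls = tibble::tibble()),
                     class = "home_range_isopleth"))
  }
  d2 <- as.matrix(stats::dist(pts))^2
  hulls <- vector("list", n)
  areas <- numeric(n)
  enclosed <- integer(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ], seq_len(n))[seq_len(k)]
    ring <- convex_hull_ring(pts[nb, , drop = FALSE])
    hulls[[i]] <- ring
    areas[i] <- ring_area(ring)
    enclosed[i] <- sum(points_in_convex(pts[, 1], pts[, 2], ring))
  }
  ord <- order(areas, -enclosed, seq_len(n))
  covered <- logical(n)
  used <- integer(0)
  target <- level * n - 1e-9
  for (i in ord) {
    used <- c(used, i)
    covered <- covered | points_in_convex(pts[, 1], pts[, 2], hulls[[i]])
    if (sum(covered) >= target) break
  }
  polygon <- hulls[used]
  structure(list(
    polygon = polygon,
    area_m2 = union_area_convex(polygon),
    level = level, k_used = k,
    n_points_covered = sum(covered), n_total = n,
    n_hulls_used = length(used),
    degenerate = all(areas[used] == 0),
    hulls = tibble::tibble(focal = ord, area = areas[ord],
                           n_enclosed = enclosed[ord],
                           used = ord %in% used)
  ), class = "home_range_isopleth")
}

#' @export
print.home_range_isopleth <- function(x, ...) {
  cat(sprintf("<home_range_isopleth> %g%% level, k = %d: %.3f km^2, %d/%d fixes covered (%d hulls)%s\n",
              100 * x$level, x$k_used, x$area_m2 / 1e6, x$n_points_covered,
              x$n_total, x$n_hulls_used,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Are points inside an isopleth polygon?
#'
#' @param iso A `home_range_isopleth`.
#' @param x,y Point coordinates (metres).
#' @return Logical vector; boundary points count as inside.
#' @export
isopleth_contains <- function(iso, x, y) {
  inside <- rep(FALSE, length(x))
  for (ring in iso$polygon) {
    inside <- inside | points_in_convex(x, y, ring)
  }
  inside
}

#' Per-interval home-range areas with greenness summaries
#'
#' For every individual and 16-day compositing interval passing the
#' daily-coverage filter, estimates the k-LoCoH isopleth, takes its
#' log-area, and summarises the greenness raster over unmasked pixels whose
#' centres fall inside the isopleth.
#'
#' @param fixes A fix tibble.
#' @param rasters List of [greenness_raster()] keyed by `period_start`.
#' @param k Hull size; `NULL` = `ceiling(sqrt(n))` per interval.
#' @param level Isopleth level (default 0.90).
#' @param min_days Coverage-filter threshold (default 15, i.e. 90% of the
#'   16-day window rounded up).
#' @param utc_offset Hours added to UTC for local dates.
#' @return Tibble with `individual_id`, `interval_start`, `n_fixes`,
#'   `k_used`, `coverage`, `area_m2`, `log_area`, `mean_greenness`,
#'   `var_greenness`, `n_pixels`. Intervals with degenerate (zero-area)
#'   isopleths or no pixels are dropped with a warning.
#' @export
homerange_series <- function(fixes, rasters, k = NULL, level = 0.90,
                             min_days = 15, utc_offset = 2) {
  seg <- segment_intervals(fixes, utc_offset)
  cov <- interval_coverage(seg, min_days = min_days)
  keep <- dplyr::semi_join(
    dplyr::filter(seg, !is.na(.data$interval_start)),
    dplyr::filter(cov, .data$pass),
    by = c("individual_id", "interval_start")
  )
  if (nrow(keep) == 0) {
    warning("no interval passes the coverage filter")
    return(tibble::tibble())
  }
  starts <- as.Date(vapply(rasters, function(r) as.character(r$period_start),
                           character(1)))
  dropped <- 0L
  out <- keep |>
    dplyr::group_by(.data$individual_id, .data$interval_start) |>
    dplyr::group_modify(function(d, key) {
      ri <- match(key$interval_start, starts)
      if (is.na(ri)) stop("no raster for compositing period starting ",
                          key$interval_start)
      kk <- if (is.null(k)) max(3L, ceiling(sqrt(nrow(d)))) else k
      if (nrow(d) < kk) { dropped <<- dropped + 1L; return(tibble::tibble()) }
      iso <- klocoh_isopleth(dplyr::mutate(d, individual_id = "z"), k = kk,
                             level = level)
      if (iso$area_m2 <= 0) { dropped <<- dropped + 1L; return(tibble::tibble()) }
      px <- raster_pixel_centres(rasters[[ri]])
      inside <- isopleth_contains(iso, px$px, px$py)
      if (!any(inside)) { dropped <<- dropped + 1L; return(tibble::tibble()) }
      g <- px$value[inside]
      tibble::tibble(
        n_fixes = nrow(d), k_used = iso$k_used,
        coverage = iso$n_points_covered / iso$n_total,
        area_m2 = iso$area_m2, log_area = log(iso$area_m2),
        mean_greenness = mean(g),
        var_greenness = if (length(g) > 1) stats::var(g) else 0,
        n_pixels = length(g)
      )
    }) |>
    dplyr::ungroup()
  if (dropped > 0) {
    warning(dropped,
            " interval(s) dropped (too few fixes, degenerate isopleth or no pixels)")
  }
  out
}

#' Random-intercept model of log home-range area on greenness
#'
#' Fits `log_area ~ mean_greenness` with a per-individual random intercept
#' ([random_intercept_model()]), the standard way to relate range size to
#' resource productivity across repeated 16-day measurements of the same
#' individuals. A negative slope means greener ranges are smaller.
#'
#' @param rows A [homerange_series()] table (>= 2 individuals, >= 10 rows).
#' @return An `ri_model`.
#' @export
area_greenness_model <- function(rows) {
  if (nrow(rows) < 10) stop("need at least 10 interval rows")
  random_intercept_model(rows$log_area, rows$mean_greenness,
                         rows$individual_id)
}

#' Write isopleths as GeoJSON
#'
#' One `MultiPolygon` feature per isopleth (the member convex hulls are the
#' polygons; their union is the isopleth region), with area, level, k and
#' coverage as properties.
#'
#' @param isos Named list of `home_range_isopleth` objects (names become the
#'   feature `id` property).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isopleth_geojson <- function(isos, path) {
  feats <- purrr::imap(isos, function(iso, id) {
    polys <- lapply(iso$polygon, function(ring) {
      closed <- rbind(ring, ring[1, , drop = FALSE])
      list(lapply(seq_len(nrow(closed)), function(i) closed[i, ]))
    })
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = polys),
         properties = list(id = id, area_m2 = iso$area_m2,
                           level = iso$level, k = iso$k_used,
                           coverage = iso$n_points_covered / iso$n_total))
  })
  fc <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
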