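#' Read a trajectory table
#'
#' Reads a CSV of GPS fixes (one row per relocation) into a tidy fix table.
#' Coordinates must already be in a metric projected CRS (e.g. a UTM zone);
#' the package does no geodesy. Rows with a duplicated
#' (individual, timestamp) key are collapsed to the first occurrence with a
#' warning, and fixes are returned in time order within each individual.
#'
#' @param path Path to a CSV with columns `individual_id`, `timestamp`
#'   (ISO 8601, interpreted as UTC), `x`, `y` (metres) and optionally `sex`.
#' @param crs_tag Free-text identifier of the metric projection the
#'   coordinates are in; stored as an attribute, never interpreted.
#' @return A tibble with columns `individual_id` (character), `t` (POSIXct,
#'   UTC), `x`, `y` (double, metres) and `sex` (character; `"unknown"` when
#'   absent), carrying the `crs_tag` attribute.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("individual_id,timestamp,x,y",
#'              "A,2012-04-01T06:00:00Z,1000,2000",
#'              "A,2012-04-01T07:00:00Z,1100,2050"), f)
#' read_trajectories(f)
#' @export
read_trajectories <- function(path, crs_tag = "local-metric") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("individual_id", "timestamp", "x", "y")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("trajectory CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(empty_fixes(crs_tag))
  }
  t <- parse_utc(raw$timestamp)
  bad <- which(is.na(t))
  if (length(bad) > 0) {
    stop("unparseable timestamp(s) in ", path, " at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  fixes <- tibble::tibble(
    individual_id = as.character(raw$individual_id),
    t = t,
    x = as.numeric(raw$x),
    y = as.numeric(raw$y),
    sex = if ("sex" %in% names(raw)) as.character(raw$sex) else "unknown"
  )
  if (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y))) {
    stop("non-finite coordinates in ", path)
  }
  dup <- duplicated(fixes[, c("individual_id", "t")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (individual, timestamp) row(s) dropped")
    fixes <- fixes[!dup, ]
  }
  fixes <- dplyr::arrange(fixes, .data$individual_id, .data$t)
  attr(fixes, "crs_tag") <- crs_tag
  fixes
}

empty_fixes <- function(crs_tag = "local-metric") {
  out <- tibble::tibble(
    individual_id = character(),
    t = as.POSIXct(character(), tz = "UTC"),
    x = numeric(), y = numeric(), sex = character()
  )
  attr(out, "crs_tag") <- crs_tag
  out
}

parse_utc <- function(s) {
  s <- gsub("Z$", "", gsub("T", " ", s))
  as.POSIXct(s, tz = "UTC", optional = TRUE,
             tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

#' Write a trajectory table to CSV
#'
#' Inverse of [read_trajectories()]; timestamps are serialised as ISO 8601 UTC
#' with whole-second precision.
#'
#' @param fixes A fix tibble (see [read_trajectories()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(fixes, path) {
  out <- data.frame(
    individual_id = fixes$individual_id,
    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = fixes$x, y = fixes$y,
    sex = if ("sex" %in% names(fixes)) fixes$sex else "unknown"
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a waterhole point table
#'
#' @param path CSV with columns `id`, `x`, `y` (metres, same projection as the
#'   fixes).
#' @return A tibble with columns `id`, `x`, `y`. Ids must be unique.
#' @export
read_waterholes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "x", "y"), names(raw))
  if (length(missing) > 0) {
    stop("waterhole CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(raw$id)) stop("waterhole ids must be unique")
  tibble::tibble(id = as.character(raw$id), x = as.numeric(raw$x),
                 y = as.numeric(raw$y))
}

#' Read / write a single-band greenness raster (ESRI ASCII grid)
#'
#' Greenness (NDVI-like) rasters are carried as a light list: a numeric matrix
#' (row 1 = northernmost row), lower-left corner, square cell size and the
#' start date of the 16-day compositing period the layer represents. The
#' plain-text ESRI ASCII grid format is used on disk.
#'
#' @param path `.asc` file path.
#' @param period_start Start date of the compositing period (`Date` or
#'   string); if `NULL`, parsed from a trailing `_YYYY-MM-DD` in the filename
#'   when present.
#' @return An object of class `greenness_raster`: list with `values` (matrix),
#'   `xll`, `yll`, `cellsize`, `nodata`, `period_start`.
#' @export
read_ascii_raster <- function(path, period_start = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  stopifnot(length(vals) == nc * nr)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  if (is.null(period_start)) {
    hit <- regmatches(path, regexpr("\\d{4}-\\d{2}-\\d{2}", path))
    if (length(hit) == 1) period_start <- as.Date(hit)
  }
  greenness_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                   cellsize = hdr$cellsize,
                   period_start = if (is.null(period_start)) NA else as.Date(period_start))
}

#' @rdname read_ascii_raster
#' @param raster A `greenness_raster` object.
#' @export
write_ascii_raster <- function(raster, path) {
  m <- raster$values
  m[is.na(m)] <- -9999
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(raster$xll, scientific = FALSE)),
    paste("yllcorner", format(raster$yll, scientific = FALSE)),
    paste("cellsize", format(raster$cellsize, scientific = FALSE)),
    "NODATA_value -9999"
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a greenness raster in memory
#'
#' @param values Numeric matrix in `[-1, 1]` (row 1 = top/north); `NA` marks
#'   masked pixels.
#' @param xll,yll Map coordinates of the lower-left corner (metres).
#' @param cellsize Square pixel edge (metres), nominally 250.
#' @param period_start Start date of the 16-day compositing period.
#' @return A `greenness_raster` object.
#' @export
greenness_raster <- function(values, xll, yll, cellsize, period_start = NA) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = -9999,
                 period_start = period_start),
            class = "greenness_raster")
}

#' @export
print.greenness_raster <- function(x, ...) {
  cat(sprintf("<greenness_raster> %d x %d pixels, %g m, origin (%g, %g), period %s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              as.character(x$period_start)))
  invisible(x)
}

#' Pixel-centre coordinates of a greenness raster
#'
#' @param raster A `greenness_raster`.
#' @return Tibble with `px`, `py` (centre coordinates, metres) and `value`;
#'   masked pixels are dropped.
#' @export
raster_pixel_centres <- function(raster) {
  m <- raster$values
  nr <- nrow(m); nc <- ncol(m)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  out <- tibble::tibble(
    px = raster$xll + (col - 0.5) * raster$cellsize,
    py = raster$yll + (nr - row + 0.5) * raster$cellsize,
    value = as.vector(m)
  )
  out[!is.na(out$value), ]
}

#' Write / read a populated grid as GeoJSON
#'
#' Serialises per-cell statistics as a GeoJSON `FeatureCollection` with one
#' square `Polygon` feature per row; all non-geometry columns become feature
#' properties. `read_grid_geojson()` round-trips the table.
#'
#' @param cells A tibble with integer columns `col`, `row` (0-based cell
#'   indices) plus any statistic columns (e.g. `nsv`, `mlsv`).
#' @param spec A [grid_spec()] describing the grid geometry.
#' @param path Output path.
#' @return `path` invisibly; `read_grid_geojson()` returns the cell tibble.
#' @export
write_grid_geojson <- function(cells, spec, path) {
  props <- cells
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    x0 <- spec$origin_x + cells$col[i] * spec$cell_size
    y0 <- spec$origin_y + cells$row[i] * spec$cell_size
    x1 <- x0 + spec$cell_size; y1 <- y0 + spec$cell_size
    ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = as.list(props[i, , drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_grid_geojson
#' @export
read_grid_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (length(fc$features) == 0) {
    return(tibble::tibble(col = integer(), row = integer()))
  }
  rows <- lapply(fc$features, function(f) {
    tibble::as_tibble(lapply(f$properties, function(v) if (is.null(v)) NA else v))
  })
  out <- dplyr::bind_rows(rows)
  out$col <- as.integer(out$col)
  out$row <- as.integer(out$row)
  out
}
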