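#' Define a square analysis grid covering a set of fixes
#'
#' The grid origin is the floor of the minimum x and y to a whole multiple of
#' `cell_size`, so cell boundaries fall on round coordinates. Cells are
#' half-open on each axis, `[origin + i*size, origin + (i+1)*size)`: a point
#' sitting exactly on a shared edge belongs to the higher-index cell, matching
#' the usual raster convention. Cell indices are 0-based.
#'
#' @param fixes A fix tibble with `x` and `y` in metres.
#' @param cell_size Cell edge in metres; the default 1000 gives 1 km^2 cells.
#' @return An object of class `grid_spec`: list with `origin_x`, `origin_y`,
#'   `cell_size`, `n_cols`, `n_rows`.
#' @examples
#' snap_grid(tibble::tibble(x = c(500, 2400), y = c(500, 900)))
#' @export
snap_grid <- function(fixes, cell_size = 1000) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (nrow(fixes) == 0) stop("need at least one fix to build a grid")
  ox <- floor(min(fixes$x) / cell_size) * cell_size
  oy <- floor(min(fixes$y) / cell_size) * cell_size
  structure(list(
    origin_x = ox, origin_y = oy, cell_size = cell_size,
    n_cols = floor((max(fixes$x) - ox) / cell_size) + 1L,
    n_rows = floor((max(fixes$y) - oy) / cell_size) + 1L
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Assign fixes (or any points) to grid cells
#'
#' Appends 0-based `col`, `row` indices and a `cell_id` string under the
#' half-open cell convention of [snap_grid()].
#'
#' @param points A tibble with `x`, `y` columns.
#' @param spec A [grid_spec()].
#' @return `points` with `col`, `row`, `cell_id` columns appended.
#' @export
assign_cells <- function(points, spec) {
  col <- floor((points$x - spec$origin_x) / spec$cell_size)
  row <- floor((points$y - spec$origin_y) / spec$cell_size)
  dplyr::mutate(points, col = as.integer(col), row = as.integer(row),
                cell_id = paste0(col, "_", row))
}
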