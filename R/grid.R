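#' Grid specification
#'
#' Describes the common raster grid every layer in an analysis shares:
#' a north-up, pixel-center-referenced grid with square pixels. Pixel
#' indexing throughout the package is 0-based and row-major; the center of
#' pixel `(row, col)` sits at
#' `x = origin_x + (col + 0.5) * pixel_size`,
#' `y = origin_y - (row + 0.5) * pixel_size`,
#' with `(origin_x, origin_y)` the top-left corner of the grid.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param pixel_size pixel edge length in map units (meters); default 30, the
#'   working resolution of the mapping framework.
#' @param origin_x,origin_y map coordinates of the top-left grid corner.
#' @param crs free-text coordinate reference system identifier (e.g.
#'   `"EPSG:32648"`); carried as metadata, never interpreted.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_size = 30,
                      origin_x = 0, origin_y = n_rows * pixel_size,
                      crs = "EPSG:32648") {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size > 0)
  structure(
    list(origin_x = origin_x, origin_y = origin_y,
         pixel_size = pixel_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs = crs),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels @ %g m, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm", x$n_rows, x$n_cols, x$pixel_size)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    identical(a$crs, b$crs)
}

#' Assert that two grids are identical
#'
#' Inputs are assumed co-registered on one grid; any mismatch is an error,
#' never a silent resample.
#'
#' @param a,b `grid_spec` objects.
#' @param what label used in the error message.
#' @return `a`, invisibly.
#' @export
check_same_grid <- function(a, b, what = "rasters") {
  if (!grids_equal(a, b)) {
    stop(sprintf("grid mismatch between %s (%s vs %s); resampling is not performed",
                 what, format(a), format(b)), call. = FALSE)
  }
  invisible(a)
}

#' Map coordinates of pixel centers
#'
#' @param grid a `grid_spec`.
#' @param row,col 0-based pixel indices (vectorized).
#' @return A two-column matrix of `x`, `y` center coordinates.
#' @export
pixel_center <- function(grid, row, col) {
  cbind(x = grid$origin_x + (col + 0.5) * grid$pixel_size,
        y = grid$origin_y - (row + 0.5) * grid$pixel_size)
}

#' Pixel indices containing map coordinates
#'
#' @param grid a `grid_spec`.
#' @param x,y map coordinates (vectorized).
#' @return A two-column integer matrix of 0-based `row`, `col` indices; points
#'   outside the grid yield `NA`.
#' @export
coord_to_pixel <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$pixel_size)
  row <- floor((grid$origin_y - y) / grid$pixel_size)
  bad <- row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}
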