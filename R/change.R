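#' Per-pixel change frequency
#'
#' Counts, per pixel, how many times the label changes between consecutive
#' maps of an ordered year sequence — the per-pixel dynamism of the land
#' cover. Pixels nodata in any year are nodata.
#'
#' @param maps ordered list (>= 2) of `lulc_labels` on one grid and level.
#' @return A list with `counts` (integer matrix in
#'   `[0, length(maps) - 1]`, `NA` = nodata) and `grid`.
#' @export
change_frequency <- function(maps) {
  stopifnot(length(maps) >= 2)
  grid <- maps[[1]]$grid
  for (m in maps[-1]) {
    check_same_grid(grid, m$grid, "label rasters")
    if (m$level != maps[[1]]$level)
      stop("maps must share one taxonomy level", call. = FALSE)
  }
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  any_na <- Reduce(`|`, lapply(maps, function(m) is.na(m$values)))
  for (i in seq_len(length(maps) - 1)) {
    counts <- counts + (maps[[i]]$values != maps[[i + 1]]$values)
  }
  counts[any_na] <- NA_integer_
  list(counts = counts, grid = grid)
}

#' Pixel area of a grid
#'
#' @param grid a [grid_spec()].
#' @return Area of one pixel in km^2 (a 30 m pixel is 9e-4 km^2).
#' @export
pixel_area_km2 <- function(grid) (grid$pixel_size / 1000)^2

#' Class-area time series
#'
#' Valid-pixel count per class and year times the pixel area. Classes
#' absent in a year get an explicit 0 row, so per-year totals always equal
#' the valid area.
#'
#' @param maps list of `lulc_labels` on one grid and level.
#' @param years numeric year labels, one per map.
#' @param pixel_area area of one pixel in km^2; default from the grid.
#' @return An `area_table` data.frame with columns `class`, `year`,
#'   `area_km2`.
#' @export
area_series <- function(maps, years, pixel_area = NULL) {
  stopifnot(length(maps) == length(years))
  pixel_area <- pixel_area %||% pixel_area_km2(maps[[1]]$grid)
  classes <- sort(unique(unlist(lapply(maps, function(m)
    unique(m$values[!is.na(m$values)])))))
  out <- do.call(rbind, lapply(seq_along(maps), function(i) {
    tab <- table(factor(maps[[i]]$values, levels = classes))
    data.frame(class = classes, year = years[i],
               area_km2 = as.numeric(tab) * pixel_area)
  }))
  structure(out, pixel_area = pixel_area,
            class = c("area_table", "data.frame"))
}

area_lookup <- function(areas, class, year) {
  i <- which(areas$class == class & areas$year == year)
  if (!length(i)) stop("no area entry for class ", class, " in ", year,
                       call. = FALSE)
  areas$area_km2[i[1]]
}

#' Annualized net-change percentage
#'
#' The percentage of net change per year between two dates:
#' `p = 100 * (A_t2 - A_t1) / (A_t1 * (t2 - t1))`; positive values are an
#' increase, negative a decrease. Undefined (`NA`) when the class had zero
#' area at `t1`.
#'
#' @param areas an `area_table` from [area_series()], or a data.frame with
#'   columns `class`, `year`, `area_km2`.
#' @param class class id (or label present in `areas$class`).
#' @param t1,t2 years with `t1 < t2`.
#' @return Percent per year (scalar).
#' @export
net_change_percent <- function(areas, class, t1, t2) {
  if (t1 >= t2) stop("t1 must precede t2", call. = FALSE)
  a1 <- area_lookup(areas, class, t1)
  a2 <- area_lookup(areas, class, t2)
  if (a1 == 0) return(NA_real_)
  100 * (a2 - a1) / (a1 * (t2 - t1))
}

#' Rescale change rates to a 0-100 dynamism rank
#'
#' Min-max rescaling of the *absolute* rates:
#' `(|r| - min|r|) / (max|r| - min|r|) * 100`, so the most dynamic class
#' scores 100 regardless of direction; signed rates should be reported
#' alongside. Degenerate input (all equal) maps to all 0.
#'
#' @param rates numeric vector of percent rates.
#' @return Vector in \[0, 100\].
#' @export
rescale_rates <- function(rates) {
  if (!length(rates)) stop("empty rate list", call. = FALSE)
  a <- abs(rates)
  rng <- range(a, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] == rng[1]) return(rep(0, length(rates)))
  (a - rng[1]) / (rng[2] - rng[1]) * 100
}

#' Class transition matrix between two dates
#'
#' Area flows `from -> to` over the pixels valid in both years; row sums
#' are the t1 class areas and column sums the t2 class areas restricted to
#' the jointly-valid mask, and the grand total is the jointly-valid area.
#'
#' @param map_t1,map_t2 `lulc_labels` on one grid and level.
#' @param pixel_area area of one pixel in km^2; default from the grid.
#' @return An object of class `transition_matrix`: K x K numeric matrix of
#'   km^2, rows = t1 class, columns = t2 class.
#' @export
transition_matrix <- function(map_t1, map_t2, pixel_area = NULL) {
  check_same_grid(map_t1$grid, map_t2$grid, "label rasters")
  if (map_t1$level != map_t2$level)
    stop("maps must share one taxonomy level", call. = FALSE)
  pixel_area <- pixel_area %||% pixel_area_km2(map_t1$grid)
  ok <- !is.na(map_t1$values) & !is.na(map_t2$values)
  classes <- sort(unique(c(map_t1$values[ok], map_t2$values[ok])))
  f <- function(x) factor(x, levels = classes)
  counts <- table(from = f(map_t1$values[ok]), to = f(map_t2$values[ok]))
  m <- unclass(counts) * pixel_area
  structure(m, classes = classes, pixel_area = pixel_area,
            class = c("transition_matrix", "matrix", "array"))
}

#' Extract Sankey flow links from a transition matrix
#'
#' @param tm a [transition_matrix()].
#' @param min_area smallest flow kept (km^2).
#' @param include_diagonal keep the unchanged (diagonal) flows too?
#' @return data.frame of `from`, `to`, `area_km2`, sorted by decreasing
#'   area — ready for Sankey plotting.
#' @export
sankey_links <- function(tm, min_area = 0, include_diagonal = FALSE) {
  stopifnot(min_area >= 0)
  classes <- attr(tm, "classes")
  m <- unclass(tm)
  idx <- which(m > 0 & m >= min_area, arr.ind = TRUE)
  if (!include_diagonal) idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  out <- data.frame(from = classes[idx[, 1]], to = classes[idx[, 2]],
                    area_km2 = m[idx])
  out[order(-out$area_km2), , drop = FALSE]
}
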