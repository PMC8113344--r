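#' @keywords internal
"_PACKAGE"

# Mask codes shared by every raster type. Cloud and shadow are treated
# identically to nodata in all statistics; the codes are kept distinct so
# reports can say why a pixel was unusable.

#' Mask codes
#'
#' Integer codes used in validity masks: `valid = 0`, `cloud = 1`,
#' `shadow = 2`, `nodata = 3`. All statistics treat every nonzero code as
#' missing.
#' @export
MASK_CODES <- c(valid = 0L, cloud = 1L, shadow = 2L, nodata = 3L)

#' Optical band names
#'
#' Canonical names of the seven optical bands: six reflective bands plus
#' thermal. The six reflective bands (`Bblue` ... `Bswir2`) are the spectral
#' signature used by harmonization and training migration.
#' @export
OPTICAL_BANDS <- c("Bblue", "Bgreen", "Bred", "Bnir", "Bswir1", "Bswir2", "Btir")

#' @rdname OPTICAL_BANDS
#' @export
REFLECTIVE_BANDS <- c("Bblue", "Bgreen", "Bred", "Bnir", "Bswir1", "Bswir2")

check_layer_shapes <- function(layers, grid, what = "band") {
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop(sprintf("%s '%s' does not match the grid shape %d x %d",
                   what, nm, grid$n_rows, grid$n_cols), call. = FALSE)
  }
  invisible(layers)
}

#' Construct an optical scene
#'
#' A scene is one dated, masked acquisition: a named list of band matrices
#' (surface reflectance, unitless; `Btir` in sensor-scaled thermal units)
#' sharing one grid, plus a four-valued validity mask (see [MASK_CODES]).
#' Reflective-band values at valid pixels are expected within a tolerant
#' surface-reflectance range of \[-0.2, 1.6\]; values outside it trigger a
#' warning, not an error, because harmonization can push saturated pixels
#' slightly out of nominal range.
#'
#' @param bands named list of numeric matrices; names must be a subset of
#'   [OPTICAL_BANDS].
#' @param date acquisition date (`Date` or parseable string).
#' @param grid a [grid_spec()].
#' @param mask integer matrix of [MASK_CODES]; `NULL` means all valid except
#'   pixels that are `NA` in any band.
#' @param sensor one of `"TM"`, `"ETM+"`, `"OLI"`, `"MSI"`.
#' @return An object of class `lulc_scene`.
#' @export
scene <- function(bands, date, grid, mask = NULL,
                  sensor = c("OLI", "TM", "ETM+", "MSI")) {
  sensor <- match.arg(sensor)
  stopifnot(is.list(bands), length(bands) >= 1)
  unknown <- setdiff(names(bands), OPTICAL_BANDS)
  if (length(unknown))
    stop("unknown band name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  check_layer_shapes(bands, grid)
  if (is.null(mask)) {
    mask <- matrix(MASK_CODES[["valid"]], grid$n_rows, grid$n_cols)
    any_na <- Reduce(`|`, lapply(bands, is.na))
    mask[any_na] <- MASK_CODES[["nodata"]]
  }
  check_layer_shapes(list(mask = mask), grid, "mask")
  storage.mode(mask) <- "integer"
  v <- mask == MASK_CODES[["valid"]]
  refl <- intersect(names(bands), REFLECTIVE_BANDS)
  vals <- unlist(lapply(bands[refl], function(b) b[v]), use.names = FALSE)
  vals <- vals[is.finite(vals)]
  if (length(vals) && (min(vals) < -0.2 || max(vals) > 1.6))
    warning("reflective-band values outside the tolerant range [-0.2, 1.6]",
            call. = FALSE)
  structure(list(bands = bands, mask = mask, date = as.Date(date),
                 sensor = sensor, grid = grid),
            class = "lulc_scene")
}

#' @export
print.lulc_scene <- function(x, ...) {
  cat(sprintf("<lulc_scene> %s %s, bands: %s, %s, %.1f%% valid\n",
              x$sensor, format(x$date), paste(names(x$bands), collapse = " "),
              format(x$grid), 100 * mean(x$mask == 0L)))
  invisible(x)
}

#' Construct a SAR scene
#'
#' One dual-polarization backscatter acquisition (`VV`, `VH`) in decibels,
#' speckled or filtered, with an orbit direction. Valid-pixel dB values are
#' expected within \[-50, 10\].
#'
#' @param vv,vh numeric matrices of backscatter in dB.
#' @param date acquisition date.
#' @param grid a [grid_spec()].
#' @param mask integer matrix of [MASK_CODES]; `NULL` means all valid except
#'   `NA` pixels.
#' @param orbit `"ascending"` or `"descending"`.
#' @return An object of class `lulc_sar_scene`.
#' @export
sar_scene <- function(vv, vh, date, grid, mask = NULL,
                      orbit = c("ascending", "descending")) {
  orbit <- match.arg(orbit)
  check_layer_shapes(list(vv = vv, vh = vh), grid)
  if (is.null(mask)) {
    mask <- matrix(MASK_CODES[["valid"]], grid$n_rows, grid$n_cols)
    mask[is.na(vv) | is.na(vh)] <- MASK_CODES[["nodata"]]
  }
  check_layer_shapes(list(mask = mask), grid, "mask")
  storage.mode(mask) <- "integer"
  v <- mask == 0L
  vals <- c(vv[v], vh[v]); vals <- vals[is.finite(vals)]
  if (length(vals) && (min(vals) < -50 || max(vals) > 10))
    warning("backscatter values outside [-50, 10] dB", call. = FALSE)
  structure(list(vv = vv, vh = vh, mask = mask, date = as.Date(date),
                 orbit = orbit, grid = grid),
            class = "lulc_sar_scene")
}

#' @export
print.lulc_sar_scene <- function(x, ...) {
  cat(sprintf("<lulc_sar_scene> %s %s orbit, %s, %.1f%% valid\n",
              format(x$date), x$orbit, format(x$grid), 100 * mean(x$mask == 0L)))
  invisible(x)
}

is_sar <- function(x) inherits(x, "lulc_sar_scene")

scene_valid <- function(x) x$mask == 0L

#' Construct a label raster
#'
#' Per-pixel integer class map at one taxonomy level; `NA` encodes nodata.
#'
#' @param values integer matrix of class ids (`NA` = nodata).
#' @param grid a [grid_spec()].
#' @param level taxonomy level of the labels (1 or 2).
#' @return An object of class `lulc_labels`.
#' @export
label_raster <- function(values, grid, level = 1L) {
  check_layer_shapes(list(labels = values), grid, "label raster")
  storage.mode(values) <- "integer"
  structure(list(values = values, grid = grid, level = as.integer(level)),
            class = "lulc_labels")
}

#' @export
print.lulc_labels <- function(x, ...) {
  tab <- table(x$values, useNA = "no")
  cat(sprintf("<lulc_labels> level %d, %s, %d classes, %.1f%% labeled\n",
              x$level, format(x$grid), length(tab),
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Display a label raster
#'
#' @param x an `lulc_labels` object.
#' @param col vector of colors, recycled over class ids.
#' @param ... passed to [graphics::image()].
#' @export
plot.lulc_labels <- function(x, col = grDevices::hcl.colors(max(x$values, na.rm = TRUE), "Spectral"), ...) {
  z <- t(x$values)[, rev(seq_len(nrow(x$values))), drop = FALSE]
  graphics::image(z, col = col, axes = FALSE, asp = nrow(x$values) / ncol(x$values), ...)
  invisible(x)
}
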