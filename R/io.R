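# Raster storage convention: multi-page 32-bit-float TIFF next to a JSON
# sidecar (<path>.json). Float TIFF pages must lie in [0, 1], so each layer
# is affinely packed into [0, 0.9] with per-layer scale/offset recorded in
# the sidecar (the scale_factor/add_offset idiom); missing pixels are stored
# as 1.0. The sidecar also carries the grid, layer names, and free metadata,
# which keeps every raster self-describing and byte-reproducible.

sidecar_path <- function(path) paste0(path, ".json")

pack_layer <- function(m) {
  fin <- is.finite(m)
  if (!any(fin)) {
    return(list(values = matrix(1, nrow(m), ncol(m)), offset = 0, scale = 1))
  }
  rng <- range(m[fin])
  scale <- max(rng[2] - rng[1], 1e-12)
  packed <- (m - rng[1]) / scale * 0.9
  packed[!fin] <- 1
  list(values = packed, offset = rng[1], scale = scale)
}

unpack_layer <- function(packed, offset, scale) {
  out <- packed / 0.9 * scale + offset
  out[packed > 0.95] <- NA_real_
  out
}

grid_to_list <- function(grid) {
  grid[c("origin_x", "origin_y", "pixel_size", "n_rows", "n_cols", "crs")]
}

grid_from_list <- function(g) {
  grid_spec(n_rows = g$n_rows, n_cols = g$n_cols, pixel_size = g$pixel_size,
            origin_x = g$origin_x, origin_y = g$origin_y, crs = g$crs)
}

#' Write a multilayer raster
#'
#' Writes named layers as a multi-page float TIFF with a JSON sidecar holding
#' the grid, layer names, and packing coefficients. `NA` pixels round-trip as
#' `NA`; values round-trip to 32-bit float precision (relative error below
#' 1e-6 of the layer range).
#'
#' @param layers named list of numeric matrices sharing the grid shape.
#' @param path output path (conventionally `.tif`); the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param grid a [grid_spec()].
#' @param metadata optional list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layers, path, grid, metadata = list()) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  check_layer_shapes(layers, grid, "layer")
  packed <- lapply(layers, pack_layer)
  tiff::writeTIFF(lapply(packed, `[[`, "values"), path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  side <- list(
    format = "annualcover-raster-v1",
    grid = grid_to_list(grid),
    layers = lapply(seq_along(packed), function(i) {
      list(name = names(layers)[i],
           offset = packed[[i]]$offset, scale = packed[[i]]$scale)
    }),
    metadata = metadata
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multilayer raster
#'
#' @param path path written by [write_raster()].
#' @return A list with `layers` (named list of matrices), `grid`, `metadata`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(sidecar_path(path)))
    stop("missing sidecar: ", sidecar_path(path), call. = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(side$layers))
    stop("sidecar lists ", length(side$layers), " layers but file has ",
         length(pages), " pages", call. = FALSE)
  layers <- lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    unpack_layer(m, side$layers[[i]]$offset, side$layers[[i]]$scale)
  })
  names(layers) <- vapply(side$layers, `[[`, "", "name")
  list(layers = layers, grid = grid_from_list(side$grid),
       metadata = side$metadata)
}

#' Write an optical or SAR scene to disk
#'
#' Bands and the validity mask are stored as raster layers; date, sensor, and
#' orbit travel in the sidecar metadata.
#'
#' @param x an `lulc_scene` or `lulc_sar_scene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(x, path) {
  if (is_sar(x)) {
    layers <- list(VV = x$vv, VH = x$vh, mask = x$mask + 0)
    meta <- list(type = "sar_scene", date = format(x$date), orbit = x$orbit)
  } else {
    layers <- c(x$bands, list(mask = x$mask + 0))
    meta <- list(type = "scene", date = format(x$date), sensor = x$sensor)
  }
  write_raster(layers, path, x$grid, metadata = meta)
}

#' Read an optical scene
#'
#' Reads a scene raster. When the file carries named layers (the native
#' convention) `band_map` is optional; for anonymous multiband files it maps
#' band names to 1-based page indices. Without a stored `mask` layer the mask
#' is derived from the nodata value: pixels equal to `nodata` (or `NA`) in
#' any band are flagged nodata, everything else is valid.
#'
#' @param path raster path.
#' @param band_map optional named integer vector, names in [OPTICAL_BANDS].
#' @param nodata optional numeric sentinel; band pixels equal to it become
#'   nodata (applied in addition to stored `NA`).
#' @param date,sensor overrides for sidecar metadata.
#' @return An `lulc_scene`.
#' @export
read_scene <- function(path, band_map = NULL, nodata = NULL,
                       date = NULL, sensor = NULL) {
  r <- read_raster(path)
  lay <- r$layers
  if (!is.null(band_map)) {
    unknown <- setdiff(names(band_map), OPTICAL_BANDS)
    if (length(unknown))
      stop("band_map names not in the band set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(band_map < 1 | band_map > length(lay)))
      stop("band_map index out of range: file has ", length(lay), " layers",
           call. = FALSE)
    bands <- lapply(band_map, function(i) lay[[i]])
    names(bands) <- names(band_map)
  } else {
    bands <- lay[intersect(names(lay), OPTICAL_BANDS)]
    if (!length(bands))
      stop("no recognizable band layers in ", path,
           "; supply band_map", call. = FALSE)
  }
  if (!is.null(nodata)) {
    for (nm in names(bands)) {
      b <- bands[[nm]]
      b[!is.na(b) & abs(b - nodata) < 1e-6 * max(1, abs(nodata))] <- NA_real_
      bands[[nm]] <- b
    }
  }
  mask <- if ("mask" %in% names(lay) && is.null(band_map)) {
    m <- round(lay[["mask"]]); m[is.na(m)] <- MASK_CODES[["nodata"]]
    storage.mode(m) <- "integer"; m
  } else NULL
  meta <- r$metadata
  scene(bands,
        date = date %||% meta$date %||% Sys.Date(),
        grid = r$grid, mask = mask,
        sensor = sensor %||% meta$sensor %||% "OLI")
}

#' Read a SAR scene
#'
#' @param path raster path holding `VV`, `VH` (and optionally `mask`) layers.
#' @return An `lulc_sar_scene`.
#' @export
read_sar_scene <- function(path) {
  r <- read_raster(path)
  lay <- r$layers
  if (!all(c("VV", "VH") %in% names(lay)))
    stop("SAR scene needs VV and VH layers", call. = FALSE)
  mask <- if ("mask" %in% names(lay)) {
    m <- round(lay[["mask"]]); m[is.na(m)] <- MASK_CODES[["nodata"]]
    storage.mode(m) <- "integer"; m
  } else NULL
  meta <- r$metadata
  sar_scene(lay$VV, lay$VH, date = meta$date %||% Sys.Date(), grid = r$grid,
            mask = mask, orbit = meta$orbit %||% "ascending")
}

#' Write a label raster
#'
#' Classes are stored as integers; nodata is encoded by a declared sentinel
#' (default 0). Reading back restores `NA` at sentinel pixels.
#'
#' @param labels an `lulc_labels`.
#' @param path output path.
#' @param sentinel integer written at nodata pixels; must not collide with a
#'   class id.
#' @return `path`, invisibly.
#' @export
write_label_raster <- function(labels, path, sentinel = 0L) {
  stopifnot(inherits(labels, "lulc_labels"))
  v <- labels$values
  if (any(v == sentinel, na.rm = TRUE))
    stop("sentinel ", sentinel, " collides with a class id", call. = FALSE)
  v[is.na(v)] <- sentinel
  write_raster(list(labels = v + 0), path, labels$grid,
               metadata = list(type = "labels", level = labels$level,
                               nodata_sentinel = sentinel))
}

#' Read a label raster
#'
#' @param path path written by [write_label_raster()].
#' @return An `lulc_labels`.
#' @export
read_label_raster <- function(path) {
  r <- read_raster(path)
  v <- round(r$layers[[1]])
  sent <- r$metadata$nodata_sentinel %||% 0L
  v[v == sent] <- NA_real_
  storage.mode(v) <- "integer"
  label_raster(v, r$grid, level = r$metadata$level %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# even-odd ray casting; ring is a matrix of x,y vertices (closed or open)
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

sample_points_df <- function(row, col, class_id, level, year, provenance) {
  structure(data.frame(row = as.integer(row), col = as.integer(col),
                       class_id = as.integer(class_id),
                       level = as.integer(level), year = as.integer(year),
                       provenance = as.character(provenance),
                       stringsAsFactors = FALSE),
            class = c("sample_points", "data.frame"))
}

#' Read labeled training/validation samples
#'
#' Accepts a CSV of points (columns `row`,`col` or `x`,`y`; `class`; optional
#' `year`, `provenance`) or a GeoJSON FeatureCollection of Point or Polygon
#' features (properties `class`, optional `year`, `provenance`). Polygons are
#' rasterized to the pixel centers they contain on `grid` (even-odd rule),
#' one record per interior pixel. Every class label is validated against the
#' taxonomy at the stated level.
#'
#' @param path CSV or GeoJSON file.
#' @param taxonomy an [lulc_taxonomy()].
#' @param grid a [grid_spec()]; required for `x`/`y` or polygon inputs.
#' @param level taxonomy level of the labels.
#' @param year default year when the file has none.
#' @param provenance default provenance (`"ground"`, `"interpreted"`,
#'   `"migrated"`).
#' @return A `sample_points` data.frame with columns `row`, `col`,
#'   `class_id`, `level`, `year`, `provenance` (0-based pixel indices).
#' @export
read_samples <- function(path, taxonomy, grid = NULL, level = 2L,
                         year = NA_integer_, provenance = "ground") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    return(read_samples_geojson(path, taxonomy, grid, level, year, provenance))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"class" %in% names(df)) stop("samples need a 'class' column", call. = FALSE)
  if (all(c("row", "col") %in% names(df))) {
    row <- df$row; col <- df$col
  } else if (all(c("x", "y") %in% names(df))) {
    if (is.null(grid)) stop("grid required to map x/y to pixels", call. = FALSE)
    rc <- coord_to_pixel(grid, df$x, df$y)
    row <- rc[, "row"]; col <- rc[, "col"]
  } else {
    stop("samples need row/col or x/y columns", call. = FALSE)
  }
  if (!is.null(grid) &&
      any(row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols,
          na.rm = TRUE))
    stop("sample location outside the grid", call. = FALSE)
  if (anyNA(row) || anyNA(col))
    stop("sample location outside the grid", call. = FALSE)
  ids <- resolve_class(taxonomy, df$class, level)
  sample_points_df(row, col, ids, level,
                   df$year %||% year, df$provenance %||% provenance)
}

read_samples_geojson <- function(path, taxonomy, grid, level, year, provenance) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features %||% stop("not a GeoJSON FeatureCollection", call. = FALSE)
  out <- list()
  for (f in feats) {
    props <- f$properties
    cls <- props$class %||% stop("feature missing 'class' property", call. = FALSE)
    yr <- props$year %||% year
    prov <- props$provenance %||% provenance
    geom <- f$geometry
    if (geom$type == "Point") {
      xy <- unlist(geom$coordinates)
      if (is.null(grid)) stop("grid required for GeoJSON samples", call. = FALSE)
      rc <- coord_to_pixel(grid, xy[1], xy[2])
      if (anyNA(rc)) stop("geometry outside the grid", call. = FALSE)
      out[[length(out) + 1L]] <- data.frame(row = rc[, "row"], col = rc[, "col"],
                                            class = cls, year = yr, prov = prov)
    } else if (geom$type == "Polygon") {
      if (is.null(grid)) stop("grid required for GeoJSON samples", call. = FALSE)
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], unlist))
      cand_r <- 0:(grid$n_rows - 1L); cand_c <- 0:(grid$n_cols - 1L)
      cc <- expand.grid(row = cand_r, col = cand_c)
      ctr <- pixel_center(grid, cc$row, cc$col)
      inside <- point_in_polygon(ctr[, "x"], ctr[, "y"], ring)
      if (any(inside))
        out[[length(out) + 1L]] <- data.frame(row = cc$row[inside],
                                              col = cc$col[inside],
                                              class = cls, year = yr, prov = prov)
    } else {
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    }
  }
  if (!length(out)) {
    return(sample_points_df(integer(), integer(), integer(), level,
                            integer(), character()))
  }
  df <- do.call(rbind, out)
  ids <- resolve_class(taxonomy, df$class, level)
  sample_points_df(df$row, df$col, ids, level, df$year, df$prov)
}

#' Write samples to CSV
#'
#' @param samples a `sample_points` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  df <- as.data.frame(samples)
  df$class <- df$class_id
  utils::write.csv(df[c("row", "col", "class", "year", "provenance")],
                   path, row.names = FALSE)
  invisible(path)
}
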