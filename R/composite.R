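#' Construct a covariate composite
#'
#' A composite is a named stack of per-pixel covariate layers reduced from a
#' season's scenes (medoid bands, deviations, percentile medoids, SAR means,
#' indices, ancillary layers) on one grid, together with the number of valid
#' observations that contributed at each pixel.
#'
#' @param layers named list of numeric matrices (`NA` = nodata).
#' @param grid a [grid_spec()].
#' @param season season label (`"dry"`, `"wet"`, or `NA`).
#' @param year season year label.
#' @param valid_count integer matrix of contributing observations per pixel.
#' @return An object of class `lulc_composite`.
#' @export
composite <- function(layers, grid, season = NA_character_,
                      year = NA_integer_, valid_count = NULL) {
  check_layer_shapes(layers, grid, "layer")
  if (is.null(valid_count)) {
    valid_count <- matrix(1L, grid$n_rows, grid$n_cols)
    valid_count[Reduce(`|`, lapply(layers, is.na))] <- 0L
  }
  storage.mode(valid_count) <- "integer"
  structure(list(layers = layers, grid = grid, season = season,
                 year = as.integer(year), valid_count = valid_count),
            class = "lulc_composite")
}

#' @export
print.lulc_composite <- function(x, ...) {
  cat(sprintf("<lulc_composite> %s %s, %d layers, %s\n",
              x$season, ifelse(is.na(x$year), "", x$year), length(x$layers),
              format(x$grid)))
  cat("  layers:", paste(names(x$layers), collapse = " "), "\n")
  invisible(x)
}

#' Season definition
#'
#' Two seasons partitioning the 12-month cycle. Defaults follow the mapping
#' framework's convention for mainland Southeast Asia: a dry season from
#' April to September and a wet season from October to March of the
#' following year. Wet-season scenes are labeled by the season's starting
#' year: an October--December date keeps its calendar year, a
#' January--March date is labeled with the previous year.
#'
#' @param dry_months,wet_months integer month vectors; together they must
#'   cover each of the 12 months exactly once.
#' @return An object of class `season_definition`.
#' @export
season_definition <- function(dry_months = 4:9, wet_months = c(10:12, 1:3)) {
  if (!setequal(c(dry_months, wet_months), 1:12) ||
      length(c(dry_months, wet_months)) != 12L)
    stop("dry and wet months must partition the 12-month cycle", call. = FALSE)
  structure(list(dry = as.integer(dry_months), wet = as.integer(wet_months),
                 wet_start = as.integer(wet_months[1])),
            class = "season_definition")
}

#' Assign a date to a (season, year) bucket
#'
#' @param date a `Date` (vectorized).
#' @param seasons a [season_definition()].
#' @return data.frame with columns `season`, `year`.
#' @export
assign_season <- function(date, seasons = season_definition()) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  season <- ifelse(m %in% seasons$dry, "dry", "wet")
  year <- ifelse(season == "wet" & m < seasons$wet_start, y - 1L, y)
  data.frame(season = season, year = as.integer(year))
}

#' Partition scenes into seasonal buckets
#'
#' @param scenes list of `lulc_scene` / `lulc_sar_scene` objects.
#' @param seasons a [season_definition()].
#' @return Named list of scene lists, keyed `"<season>_<year>"`; empty
#'   buckets are simply absent.
#' @export
partition_by_season <- function(scenes, seasons = season_definition()) {
  if (!length(scenes)) return(list())
  dates <- as.Date(vapply(scenes, function(s) format(s$date), ""))
  sy <- assign_season(dates, seasons)
  key <- paste0(sy$season, "_", sy$year)
  split(scenes, factor(key, levels = unique(key)))
}

# --- stack helpers ------------------------------------------------------

# bands: list over scenes of named band lists -> per-band [r, c, s] arrays
scene_stack <- function(scenes, bands) {
  grid <- scenes[[1]]$grid
  for (s in scenes[-1]) check_same_grid(grid, s$grid, "scenes")
  n <- length(scenes)
  get_band <- function(s, b) {
    if (is_sar(s)) switch(b, VV = s$vv, VH = s$vh,
                          stop("unknown SAR band ", b, call. = FALSE))
    else s$bands[[b]] %||% stop("scene lacks band ", b, call. = FALSE)
  }
  arrs <- lapply(bands, function(b) {
    a <- array(NA_real_, c(grid$n_rows, grid$n_cols, n))
    for (i in seq_len(n)) a[, , i] <- get_band(scenes[[i]], b)
    a
  })
  names(arrs) <- bands
  valid <- array(FALSE, c(grid$n_rows, grid$n_cols, n))
  for (i in seq_len(n)) {
    v <- scene_valid(scenes[[i]])
    for (b in bands) v <- v & !is.na(arrs[[b]][, , i])
    valid[, , i] <- v
  }
  list(arrs = arrs, valid = valid, grid = grid, n = n)
}

# per-pixel index (into 1..n) of the observation minimizing the sum of
# Euclidean distances to all other valid observations; NA where none valid
medoid_index <- function(stack) {
  n <- stack$n; valid <- stack$valid
  nr <- dim(valid)[1]; nc <- dim(valid)[2]
  if (n == 1L) {
    idx <- matrix(1L, nr, nc); idx[!valid[, , 1]] <- NA_integer_
    return(idx)
  }
  S <- array(0, c(nr, nc, n))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- 0
      for (b in names(stack$arrs)) {
        a <- stack$arrs[[b]]
        d2 <- d2 + (a[, , i] - a[, , j])^2
      }
      d <- sqrt(d2)
      d[!(valid[, , i] & valid[, , j])] <- 0
      d[is.na(d)] <- 0
      S[, , i] <- S[, , i] + d
      S[, , j] <- S[, , j] + d
    }
  }
  S[!valid] <- Inf
  flat <- matrix(S, nr * nc, n)
  # exact distance-sum ties (duplicate observations, two-scene stacks) are
  # broken lexicographically on the band values so the choice is invariant
  # to scene ordering
  smin <- do.call(pmin, lapply(seq_len(n), function(i) flat[, i]))
  cand <- flat <= smin * (1 + 1e-12) + 1e-300
  for (b in names(stack$arrs)) {
    v <- matrix(stack$arrs[[b]], nr * nc, n)
    v[!cand | is.na(v)] <- Inf
    vmin <- do.call(pmin, lapply(seq_len(n), function(i) v[, i]))
    cand <- cand & (v <= vmin)
    if (all(rowSums(cand) <= 1L)) break
  }
  idx <- max.col(cand, ties.method = "first")
  idx[!is.finite(smin)] <- NA_integer_
  matrix(as.integer(idx), nr, nc)
}

pick_by_index <- function(arr, idx) {
  nr <- nrow(idx); nc <- ncol(idx)
  flat <- matrix(arr, nr * nc, dim(arr)[3])
  out <- flat[cbind(seq_len(nr * nc), as.vector(idx))]
  matrix(out, nr, nc)
}

#' Medoid composite
#'
#' Per pixel, selects the scene observation (full band vector, restricted to
#' observations valid at that pixel) minimizing the sum of Euclidean
#' distances to all other valid observations there, and copies its band
#' values into the composite. A single valid observation is its own medoid;
#' pixels with none are nodata. The medoid is always an actual observation,
#' which avoids the between-date mixing artifacts of mean or median
#' compositing.
#'
#' @param scenes nonempty list of scenes on one grid.
#' @param bands band names to composite (and to measure distance over).
#' @param layer_prefix prefix for output layer names (default `"medoid_"`).
#' @return An `lulc_composite` with one `medoid_<band>` layer per band.
#' @export
medoid_composite <- function(scenes, bands = REFLECTIVE_BANDS,
                             layer_prefix = "medoid_") {
  if (!length(scenes)) stop("empty scene list", call. = FALSE)
  st <- scene_stack(scenes, bands)
  idx <- medoid_index(st)
  layers <- lapply(st$arrs, pick_by_index, idx = idx)
  names(layers) <- paste0(layer_prefix, bands)
  vc <- apply(st$valid, c(1, 2), sum)
  composite(layers, st$grid, valid_count = vc)
}

# ranking signal for percentile selection: NDVI when nir and red are in the
# stack, otherwise the mean over the composited bands
rank_signal <- function(stack) {
  b <- names(stack$arrs)
  if (all(c("Bnir", "Bred") %in% b)) {
    nir <- stack$arrs[["Bnir"]]; red <- stack$arrs[["Bred"]]
    den <- nir + red
    v <- (nir - red) / den
    v[abs(den) < 1e-9] <- NA_real_
    v
  } else {
    Reduce(`+`, stack$arrs) / length(stack$arrs)
  }
}

#' Percentile-medoid composite
#'
#' Targets the seasonal extremes of the observation stack while keeping
#' medoid semantics: per pixel, valid observations are ranked by NDVI (or by
#' their band mean when NDVI's bands are absent), a window of
#' `ceiling(n / 3)` observations is centered on the nearest-rank `q`-th
#' percentile position `round(1 + (n - 1) * q / 100)`, and the medoid of the
#' windowed observations is returned. With two or fewer valid observations
#' the plain medoid is used. Ties inside the window resolve to the
#' observation whose rank is closest to the percentile position.
#'
#' @param scenes nonempty list of scenes on one grid.
#' @param bands band names to composite.
#' @param q percentile in (0, 100); the framework uses 20 and 80.
#' @param window_fraction fraction of the valid observations included in the
#'   percentile window (default 1/3).
#' @return An `lulc_composite` with `p<q>_<band>` layers.
#' @export
percentile_medoid_composite <- function(scenes, bands = REFLECTIVE_BANDS,
                                        q = 20, window_fraction = 1 / 3) {
  if (!length(scenes)) stop("empty scene list", call. = FALSE)
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)", call. = FALSE)
  need <- unique(c(bands,
                   intersect(c("Bnir", "Bred"),
                             if (is_sar(scenes[[1]])) character() else
                               names(scenes[[1]]$bands))))
  st <- scene_stack(scenes, need)
  sig <- rank_signal(st)
  nr <- st$grid$n_rows; nc <- st$grid$n_cols; n <- st$n
  npix <- nr * nc
  sig_m <- matrix(sig, npix, n)
  valid_m <- matrix(st$valid, npix, n)
  sig_m[!valid_m] <- NA_real_
  band_m <- lapply(st$arrs[bands], function(a) matrix(a, npix, n))
  out <- lapply(bands, function(b) rep(NA_real_, npix))
  names(out) <- bands
  for (p in seq_len(npix)) {
    vi <- which(valid_m[p, ])
    k <- length(vi)
    if (k == 0L) next
    if (k > 2L) {
      ord <- vi[order(sig_m[p, vi])]
      center <- floor(1 + (k - 1) * q / 100 + 0.5)
      w <- max(1L, ceiling(k * window_fraction))
      start <- min(max(center - floor((w - 1) / 2), 1L), k - w + 1L)
      ranks <- start:(start + w - 1L)
      sel <- ord[ranks]
    } else {
      sel <- vi
      center <- 1L
      ranks <- seq_along(sel)
    }
    if (length(sel) == 1L) {
      for (b in bands) out[[b]][p] <- band_m[[b]][p, sel]
      next
    }
    X <- vapply(bands, function(b) band_m[[b]][p, sel], numeric(length(sel)))
    if (is.null(dim(X))) X <- matrix(X, nrow = length(sel))
    D <- as.matrix(stats::dist(X))
    sums <- rowSums(D)
    best <- which(sums == min(sums))
    if (length(best) > 1L) best <- best[order(abs(ranks[best] - center), ranks[best])][1]
    pick <- sel[best[1]]
    for (b in bands) out[[b]][p] <- band_m[[b]][p, pick]
  }
  layers <- lapply(out, matrix, nrow = nr, ncol = nc)
  names(layers) <- paste0("p", q, "_", bands)
  vc <- matrix(rowSums(valid_m), nr, nc)
  composite(layers, st$grid, valid_count = vc)
}

#' Per-band standard-deviation composite
#'
#' Population standard deviation (divisor `n`) of each band over the valid
#' observations at each pixel; pixels with fewer than two observations get
#' 0, pixels with none are nodata.
#'
#' @inheritParams medoid_composite
#' @return An `lulc_composite` with `std_<band>` layers.
#' @export
stddev_composite <- function(scenes, bands = REFLECTIVE_BANDS) {
  if (!length(scenes)) stop("empty scene list", call. = FALSE)
  st <- scene_stack(scenes, bands)
  vc <- apply(st$valid, c(1, 2), sum)
  layers <- lapply(st$arrs, function(a) {
    a[!st$valid] <- NA_real_
    s1 <- apply(a, c(1, 2), sum, na.rm = TRUE)
    s2 <- apply(a^2, c(1, 2), sum, na.rm = TRUE)
    v <- s2 / vc - (s1 / vc)^2
    out <- sqrt(pmax(v, 0))
    out[vc < 2] <- 0
    out[vc == 0] <- NA_real_
    out
  })
  names(layers) <- paste0("std_", bands)
  composite(layers, st$grid, valid_count = vc)
}

#' Seasonal SAR covariates
#'
#' Arithmetic seasonal means of VV and VH backscatter (dB) over valid
#' observations, plus the normalized polarization difference
#' `nd_VHVV = (VH - VV) / (VH + VV)` computed from the seasonal means
#' (computing it from means rather than per scene leaves fewer nodata
#' holes). Ascending and descending orbits are kept as separate layers
#' (suffixed `_asc` / `_desc`) when both are present.
#'
#' @param scenes nonempty list of `lulc_sar_scene` objects on one grid.
#' @param per_scene_nd if `TRUE`, `nd_VHVV` is computed per scene and then
#'   averaged.
#' @return An `lulc_composite` with `mean_VV`, `mean_VH`, `nd_VHVV` layers
#'   (per orbit where applicable).
#' @export
sar_seasonal_covariates <- function(scenes, per_scene_nd = FALSE) {
  if (!length(scenes)) stop("empty scene list", call. = FALSE)
  stopifnot(all(vapply(scenes, is_sar, TRUE)))
  orbits <- vapply(scenes, `[[`, "", "orbit")
  groups <- split(scenes, orbits)
  suffix <- if (length(groups) > 1L)
    c(ascending = "_asc", descending = "_desc") else
    stats::setNames("", names(groups))
  layers <- list()
  vc_all <- NULL
  for (orb in names(groups)) {
    st <- scene_stack(groups[[orb]], c("VV", "VH"))
    vc <- apply(st$valid, c(1, 2), sum)
    mean_band <- function(b) {
      a <- st$arrs[[b]]
      a[!st$valid] <- NA_real_
      s <- apply(a, c(1, 2), sum, na.rm = TRUE)
      out <- s / vc
      out[vc == 0] <- NA_real_
      out
    }
    mvv <- mean_band("VV"); mvh <- mean_band("VH")
    if (per_scene_nd) {
      a <- (st$arrs[["VH"]] - st$arrs[["VV"]]) / (st$arrs[["VH"]] + st$arrs[["VV"]])
      a[abs(st$arrs[["VH"]] + st$arrs[["VV"]]) < 1e-9] <- NA_real_
      a[!st$valid] <- NA_real_
      s <- apply(a, c(1, 2), sum, na.rm = TRUE)
      cnt <- apply(!is.na(a), c(1, 2), sum)
      nd <- s / cnt; nd[cnt == 0] <- NA_real_
    } else {
      den <- mvh + mvv
      nd <- (mvh - mvv) / den
      nd[!is.na(den) & abs(den) < 1e-9] <- NA_real_
    }
    sfx <- suffix[[orb]]
    layers[[paste0("mean_VV", sfx)]] <- mvv
    layers[[paste0("mean_VH", sfx)]] <- mvh
    layers[[paste0("nd_VHVV", sfx)]] <- nd
    vc_all <- if (is.null(vc_all)) vc else vc_all + vc
  }
  composite(layers, scenes[[1]]$grid, valid_count = vc_all)
}

# mask-aware local window statistics via integral images; windows are
# clipped at image edges
box_stats <- function(m, valid, w) {
  h <- (w - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  m0 <- m; m0[!valid] <- 0
  isum <- function(x) {
    cs <- apply(apply(x, 2, cumsum), 1, cumsum) # t(integral)
    t(cs)
  }
  S <- isum(m0); S2 <- isum(m0^2); C <- isum(valid + 0)
  at <- function(I, r, c) {
    out <- matrix(0, length(r), length(c))
    ok_r <- r >= 1; ok_c <- c >= 1
    rr <- pmax(r, 1); cc <- pmax(c, 1)
    out <- I[rr, cc, drop = FALSE]
    out[!ok_r, ] <- 0; out[, !ok_c] <- 0
    out
  }
  r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
  win_sum <- function(I) {
    at(I, r2, c2) - at(I, r1 - 1, c2) - at(I, r2, c1 - 1) + at(I, r1 - 1, c1 - 1)
  }
  cnt <- win_sum(C)
  s <- win_sum(S); s2 <- win_sum(S2)
  mu <- s / cnt; mu[cnt == 0] <- NA_real_
  v <- s2 / cnt - mu^2
  v <- pmax(v, 0); v[cnt == 0] <- NA_real_
  list(mean = mu, var = v, count = cnt)
}

#' Lee speckle filter
#'
#' The classic adaptive Lee filter:
#' `out = mean + W * (in - mean)` with `W = var / (var + noise_var)`, where
#' `mean` and `var` are local-window statistics over valid pixels. Flat
#' areas collapse to the local mean while point targets, edges, and texture
#' are preserved. The noise variance defaults to the mean of the local
#' variances over the image, a standard image-wide speckle estimate.
#'
#' @param x an `lulc_sar_scene` (both polarizations filtered) or a plain
#'   numeric matrix.
#' @param window odd window edge length, `>= 3`.
#' @param noise_var speckle noise variance; `NULL` for the image-wide
#'   default.
#' @return The filtered object, same class as `x`; mask preserved.
#' @export
lee_filter <- function(x, window = 5L, noise_var = NULL) {
  if (window < 3 || window %% 2 == 0)
    stop("window must be odd and >= 3", call. = FALSE)
  filt <- function(m, valid) {
    bs <- box_stats(m, valid, window)
    nv <- noise_var %||% mean(bs$var[valid & bs$count >= 2], na.rm = TRUE)
    den <- bs$var + nv
    W <- ifelse(is.na(den) | den <= 0, 0, bs$var / den)
    out <- bs$mean + W * (m - bs$mean)
    out[!valid] <- m[!valid]
    out
  }
  if (is_sar(x)) {
    v <- scene_valid(x)
    sar_scene(filt(x$vv, v), filt(x$vh, v), date = x$date, grid = x$grid,
              mask = x$mask, orbit = x$orbit)
  } else {
    filt(x, !is.na(x))
  }
}

#' Terrain covariates from a DEM
#'
#' Slope and aspect by Horn's eight-neighbor finite differences on the
#' working grid, plus the elevation itself. Aspect is reported in degrees
#' clockwise from north of the **down-slope** direction, in `[0, 360)`;
#' flat cells (zero gradient) have nodata aspect. Edge pixels use
#' edge-replicated padding.
#'
#' @param dem numeric elevation matrix (meters) on `grid`.
#' @param grid a [grid_spec()]; the pixel size sets the gradient scale.
#' @return An `lulc_composite` with layers `elevation`, `slope` (degrees),
#'   `aspect` (degrees).
#' @export
terrain_covariates <- function(dem, grid) {
  if (nrow(dem) < 3 || ncol(dem) < 3)
    stop("DEM must be at least 3 x 3", call. = FALSE)
  check_layer_shapes(list(dem = dem), grid, "DEM")
  nr <- nrow(dem); nc <- ncol(dem)
  pad <- rbind(dem[1, , drop = FALSE], dem, dem[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  a <- sh(-1, -1); b <- sh(-1, 0); cc <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  cell <- grid$pixel_size
  dz_de <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cell)  # east
  dz_dn <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cell)  # north
  slope <- atan(sqrt(dz_de^2 + dz_dn^2)) * 180 / pi
  aspect <- (atan2(-dz_de, -dz_dn) * 180 / pi) %% 360
  aspect[dz_de == 0 & dz_dn == 0] <- NA_real_
  composite(list(elevation = dem, slope = slope, aspect = aspect), grid,
            valid_count = matrix(1L, nr, nc))
}
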