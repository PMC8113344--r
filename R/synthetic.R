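# Synthetic study conditions: Gaussian band noise, independent across
# bands; class means drawn to a requested spectral separation (in noise-SD
# units); seasonal offsets; patchy rectangular clouds; optional planted
# between-year class change. Everything is deterministic under a seed, so
# each pipeline stage can be tested against known truth without downloads.

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic per-class spectra model
#'
#' Draws a spectral model for a set of classes: a six-band mean reflectance
#' vector per class, a wet-season offset vector, SAR backscatter means
#' (VV, VH in dB), a thermal mean, and per-band noise SDs. Class means are
#' redrawn until the minimum pairwise Euclidean separation, measured in
#' units of the band noise SD, reaches `separation` (bounded retries, then
#' error). Deterministic by seed.
#'
#' @param classes integer class ids, a class count, or an
#'   [lulc_taxonomy()] (level-2 ids).
#' @param separation required minimum between-class mean separation in
#'   noise-SD units; 5 puts classes comfortably apart of the band noise.
#' @param noise_sd Gaussian band noise SD (reflectance units).
#' @param sar_noise_sd SAR noise SD (dB).
#' @param seed integer seed.
#' @return An object of class `class_spectra_model` with element
#'   `separation_achieved`.
#' @export
make_class_spectra <- function(classes, separation = 5, noise_sd = 0.02,
                               sar_noise_sd = 1.0, seed = 1L) {
  stopifnot(separation > 0)
  ids <- if (inherits(classes, "lulc_taxonomy")) classes$level2$id
         else if (length(classes) == 1L && classes >= 1) seq_len(classes)
         else as.integer(classes)
  K <- length(ids)
  model <- with_seed(seed, {
    means <- NULL
    min_sep <- -Inf
    for (try in seq_len(200L)) {
      cand <- matrix(stats::runif(K * 6, 0.05, 0.55), K, 6,
                     dimnames = list(ids, REFLECTIVE_BANDS))
      d <- min(stats::dist(cand)) / noise_sd
      if (d > min_sep) { means <- cand; min_sep <- d }
      if (min_sep >= separation) break
    }
    if (min_sep < separation)
      stop("could not draw ", K, " class means at separation ", separation,
           " after bounded retries", call. = FALSE)
    list(
      class_ids = ids,
      means = means,
      seasonal_offset = matrix(stats::runif(K * 6, -0.03, 0.03), K, 6,
                               dimnames = list(ids, REFLECTIVE_BANDS)),
      sar_means = {
        vv <- stats::runif(K, -14, -6)
        cbind(VV = vv, VH = vv - stats::runif(K, 5, 9))
      },
      sar_seasonal_offset = stats::runif(K, -1, 1),
      thermal_mean = stats::runif(K, 0.3, 0.6),
      noise_sd = noise_sd, sar_noise_sd = sar_noise_sd,
      thermal_noise_sd = 0.01,
      separation_achieved = min_sep, seed = seed
    )
  })
  structure(model, class = "class_spectra_model")
}

#' @export
print.class_spectra_model <- function(x, ...) {
  cat(sprintf(paste0("<class_spectra_model> %d classes, noise sd %.3g, ",
                     "min separation %.1f SD\n"),
              length(x$class_ids), x$noise_sd, x$separation_achieved))
  invisible(x)
}

#' Synthetic class geometry
#'
#' A blocky truth label map built from the Voronoi diagram of random seed
#' points (classes cycle over the seeds so each class is present), giving
#' contiguous patches rather than salt-and-pepper labels.
#'
#' @param grid a [grid_spec()].
#' @param class_ids class ids to place.
#' @param patches_per_class Voronoi seeds per class.
#' @param seed integer seed.
#' @param level taxonomy level tag.
#' @return An [label_raster()].
#' @export
simulate_label_map <- function(grid, class_ids, patches_per_class = 3L,
                               seed = 1L, level = 2L) {
  K <- length(class_ids)
  n_seed <- K * patches_per_class
  with_seed(seed, {
    sr <- stats::runif(n_seed, 0, grid$n_rows)
    sc <- stats::runif(n_seed, 0, grid$n_cols)
    cls <- rep(class_ids, length.out = n_seed)[sample.int(n_seed)]
    rows <- matrix(seq_len(grid$n_rows) - 0.5, grid$n_rows, grid$n_cols)
    cols <- matrix(rep(seq_len(grid$n_cols) - 0.5, each = grid$n_rows),
                   grid$n_rows, grid$n_cols)
    best_d <- matrix(Inf, grid$n_rows, grid$n_cols)
    lab <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
    for (i in seq_len(n_seed)) {
      d <- (rows - sr[i])^2 + (cols - sc[i])^2
      upd <- d < best_d
      best_d[upd] <- d[upd]
      lab[upd] <- cls[i]
    }
    label_raster(lab, grid, level = level)
  })
}

# patchy cloud/shadow mask: random rectangles until the masked fraction
# reaches the target
cloud_mask <- function(grid, cloud_fraction) {
  mask <- matrix(MASK_CODES[["valid"]], grid$n_rows, grid$n_cols)
  if (cloud_fraction <= 0) return(mask)
  npix <- grid$n_rows * grid$n_cols
  guard <- 0L
  while (mean(mask != 0L) < cloud_fraction && guard < 1000L) {
    h <- max(2L, round(stats::runif(1, 0.05, 0.25) * grid$n_rows))
    w <- max(2L, round(stats::runif(1, 0.05, 0.25) * grid$n_cols))
    r0 <- sample.int(grid$n_rows - h + 1L, 1L)
    c0 <- sample.int(grid$n_cols - w + 1L, 1L)
    code <- sample(c(MASK_CODES[["cloud"]], MASK_CODES[["shadow"]]), 1L,
                   prob = c(0.8, 0.2))
    mask[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- code
    guard <- guard + 1L
  }
  mask
}

class_field <- function(values_by_class, label_values, class_ids) {
  idx <- match(label_values, class_ids)
  matrix(values_by_class[idx], nrow(label_values), ncol(label_values))
}

#' Simulate one year of scenes
#'
#' Generates the four seasonal scene sets of one year from a spectra model
#' and a truth label map: per optical scene, pixel values are the class
#' mean (plus the seasonal offset in the wet season) plus independent
#' Gaussian band noise, under a patchy rectangular cloud/shadow mask of
#' the requested expected fraction; SAR scenes draw from the class dB
#' means with their own noise and are unaffected by clouds.
#'
#' @param model a [make_class_spectra()] model.
#' @param label_map truth [label_raster()].
#' @param year simulated year.
#' @param scenes_per_season optical and SAR scenes per season.
#' @param cloud_fraction expected masked fraction per optical scene, in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @return A list with `optical` and `sar`, each a list of `dry` / `wet`
#'   scene lists, plus `year`.
#' @export
simulate_year <- function(model, label_map, year, scenes_per_season = 3L,
                          cloud_fraction = 0.2, seed = 1L) {
  stopifnot(cloud_fraction >= 0, cloud_fraction < 1)
  if (all(is.na(label_map$values))) stop("empty label map", call. = FALSE)
  grid <- label_map$grid
  lv <- label_map$values
  ids <- model$class_ids
  noise <- function(sd) matrix(stats::rnorm(grid$n_rows * grid$n_cols, 0, sd),
                               grid$n_rows, grid$n_cols)
  month_of <- function(season, i) {
    months <- if (season == "dry") 4:9 else c(10:12, 1:3)
    months[(i - 1L) %% 6L + 1L]
  }
  with_seed(seed, {
    optical <- list(); sar <- list()
    for (season in c("dry", "wet")) {
      osc <- list(); ssc <- list()
      for (i in seq_len(scenes_per_season)) {
        m <- month_of(season, i)
        y <- if (season == "wet" && m < 10) year + 1L else year
        date <- as.Date(sprintf("%04d-%02d-15", y, m))
        bands <- lapply(REFLECTIVE_BANDS, function(b) {
          mu <- model$means[, b]
          if (season == "wet") mu <- mu + model$seasonal_offset[, b]
          class_field(mu, lv, ids) + noise(model$noise_sd)
        })
        names(bands) <- REFLECTIVE_BANDS
        bands$Btir <- class_field(model$thermal_mean, lv, ids) +
          noise(model$thermal_noise_sd)
        mask <- cloud_mask(grid, cloud_fraction)
        mask[is.na(lv)] <- MASK_CODES[["nodata"]]
        osc[[i]] <- scene(bands, date = date, grid = grid, mask = mask,
                          sensor = "OLI")
        svv <- class_field(model$sar_means[, "VV"], lv, ids)
        svh <- class_field(model$sar_means[, "VH"], lv, ids)
        if (season == "wet") {
          off <- class_field(model$sar_seasonal_offset, lv, ids)
          svv <- svv + off; svh <- svh + off
        }
        smask <- matrix(MASK_CODES[["valid"]], grid$n_rows, grid$n_cols)
        smask[is.na(lv)] <- MASK_CODES[["nodata"]]
        ssc[[i]] <- sar_scene(svv + noise(model$sar_noise_sd),
                              svh + noise(model$sar_noise_sd),
                              date = date, grid = grid, mask = smask,
                              orbit = "ascending")
      }
      optical[[season]] <- osc
      sar[[season]] <- ssc
    }
    list(optical = optical, sar = sar, year = year)
  })
}

#' Change script
#'
#' Declares planted between-year class changes: in `year`, a random
#' `fraction` of the pixels currently labeled `from` becomes `to`.
#'
#' @param year,from,to,fraction equal-length vectors (fractions in
#'   \[0, 1\]).
#' @return A `change_script` data.frame.
#' @export
change_script <- function(year = integer(), from = integer(),
                          to = integer(), fraction = numeric()) {
  stopifnot(all(fraction >= 0), all(fraction <= 1))
  structure(data.frame(year = as.integer(year), from = as.integer(from),
                       to = as.integer(to), fraction = fraction),
            class = c("change_script", "data.frame"))
}

#' Apply a change script to a truth map
#'
#' Produces the truth label series over `years`: at each scripted year the
#' requested fraction of the `from`-class pixels flips to `to` (uniformly
#' at random, seeded) and the change persists in later years; unscripted
#' pixels keep identical labels across the whole series.
#'
#' @param label_map starting [label_raster()].
#' @param script a [change_script()]; years must lie within `years`.
#' @param years ascending years of the series (first year = `label_map`).
#' @param seed integer seed.
#' @return Named list of `lulc_labels`, one per year.
#' @export
apply_change_script <- function(label_map, script, years, seed = 1L) {
  stopifnot(all(diff(years) > 0))
  if (nrow(script) && !all(script$year %in% years))
    stop("script year outside the simulated range", call. = FALSE)
  known <- unique(label_map$values[!is.na(label_map$values)])
  if (nrow(script) && !all(c(script$from, script$to) %in% known))
    stop("unknown class in change script", call. = FALSE)
  with_seed(seed, {
    out <- list()
    current <- label_map$values
    for (y in years) {
      todo <- script[script$year == y, , drop = FALSE]
      for (i in seq_len(nrow(todo))) {
        cand <- which(current == todo$from[i])
        n <- round(length(cand) * todo$fraction[i])
        if (n > 0) current[sample(cand, n)] <- todo$to[i]
      }
      out[[as.character(y)]] <- label_raster(current, label_map$grid,
                                             level = label_map$level)
    }
    out
  })
}

#' Draw training samples from a truth map
#'
#' Uniform per-class sampling of truth pixels, stamped as ground samples
#' of `year`. A disjoint held-out set for validation can be drawn with a
#' different seed and [setdiff_samples()].
#'
#' @param truth an `lulc_labels` truth map.
#' @param n_per_class samples per class.
#' @param year stamped year.
#' @param seed integer seed.
#' @return A `sample_points` data.frame with `provenance = "ground"`.
#' @export
sample_training <- function(truth, n_per_class, year = NA_integer_,
                            seed = 1L) {
  pts <- stratified_sample(truth, n_per_class, seed = seed)
  pts$year <- as.integer(year)
  pts$provenance <- "ground"
  pts
}

#' Remove overlapping sample locations
#'
#' @param x,y `sample_points` data.frames.
#' @return Rows of `x` whose (row, col) location does not occur in `y`.
#' @export
setdiff_samples <- function(x, y) {
  key <- function(d) paste(d$row, d$col)
  x[!(key(x) %in% key(y)), , drop = FALSE]
}
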