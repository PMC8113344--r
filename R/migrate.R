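#' Euclidean spectral distance
#'
#' `sqrt(sum((x - y)^2))` over the six reflective bands: the straight-line
#' distance between two pixels' band vectors, sensitive to brightness
#' change. Vectorized over rows when given matrices.
#'
#' @param x,y numeric vectors of equal length, or matrices with one
#'   signature per row.
#' @return A scalar, or a vector with one distance per row.
#' @export
euclidean_distance <- function(x, y) {
  x <- rbind(x); y <- rbind(y)
  if (!all(dim(x) == dim(y)))
    stop("signature length mismatch", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite signature values", call. = FALSE)
  d <- sqrt(rowSums((x - y)^2))
  if (length(d) == 1L) unname(d[1]) else unname(d)
}

#' Spectral angle distance
#'
#' `arccos(sum(x * y) / sqrt(sum(x^2) * sum(y^2)))` in radians, in
#' `[0, pi]`: the angle between two band vectors, invariant to positive
#' brightness scaling of either vector and hence sensitive only to spectral
#' shape change. Vectorized over rows when given matrices.
#'
#' @param x,y numeric vectors of equal length (nonzero norm), or matrices
#'   with one signature per row.
#' @return Angle(s) in radians.
#' @export
spectral_angle <- function(x, y) {
  x <- rbind(x); y <- rbind(y)
  if (!all(dim(x) == dim(y)))
    stop("signature length mismatch", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite signature values", call. = FALSE)
  nx <- sqrt(rowSums(x^2)); ny <- sqrt(rowSums(y^2))
  if (any(nx == 0) || any(ny == 0))
    stop("zero-norm signature", call. = FALSE)
  cosang <- rowSums(x * y) / (nx * ny)
  a <- acos(pmin(pmax(cosang, -1), 1))
  if (length(a) == 1L) unname(a[1]) else unname(a)
}

#' Migration rule
#'
#' Decision rule declaring a training pixel "unchanged" between the
#' reference and a target year. The published thresholds are 0.05
#' (Euclidean distance, reflectance units) and 0.95 (spectral angle
#' criterion). The 0.95 is ambiguous between an angle in radians and a
#' cosine similarity, so both readings are implemented:
#' `sad_interpretation = "angle_radians"` retains a sample iff
#' `SAD <= sad_threshold` (the literal reading, the default), while
#' `"cosine_similarity"` retains iff `cos(SAD) >= sad_threshold`
#' (i.e. `SAD <= acos(0.95) ~ 0.318` rad). Comparisons are inclusive.
#'
#' @param ed_threshold Euclidean-distance threshold (> 0), reflectance
#'   units.
#' @param sad_threshold spectral-angle criterion threshold.
#' @param sad_interpretation `"angle_radians"` or `"cosine_similarity"`.
#' @param combiner `"AND"` (both criteria must pass; conservative default)
#'   or `"OR"`.
#' @return An object of class `migration_rule`.
#' @export
migration_rule <- function(ed_threshold = 0.05, sad_threshold = 0.95,
                           sad_interpretation = c("angle_radians",
                                                  "cosine_similarity"),
                           combiner = c("AND", "OR")) {
  stopifnot(ed_threshold > 0, is.finite(sad_threshold))
  structure(list(ed_threshold = ed_threshold, sad_threshold = sad_threshold,
                 sad_interpretation = match.arg(sad_interpretation),
                 combiner = match.arg(combiner)),
            class = "migration_rule")
}

rule_keep <- function(rule, ed, sad) {
  # inclusive comparisons, with a relative epsilon so exact-boundary cases
  # are not lost to floating-point round-off
  eps <- 1e-9
  keep_ed <- ed <= rule$ed_threshold * (1 + eps)
  keep_sad <- if (rule$sad_interpretation == "angle_radians")
    sad <= rule$sad_threshold * (1 + eps) else
    cos(sad) >= rule$sad_threshold * (1 - eps)
  if (rule$combiner == "AND") keep_ed & keep_sad else keep_ed | keep_sad
}

signature_matrix <- function(comp, rows, cols, prefix = "medoid_") {
  b <- composite_bands(comp, prefix)
  missing_b <- setdiff(REFLECTIVE_BANDS, names(b))
  if (length(missing_b))
    stop("composite lacks signature band(s): ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  idx <- cbind(rows + 1L, cols + 1L)
  out <- vapply(REFLECTIVE_BANDS, function(nm) b[[nm]][idx],
                numeric(length(rows)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(rows))
  colnames(out) <- REFLECTIVE_BANDS
  out
}

#' Migrate training samples across years
#'
#' The automatic training migration model: reference-year training pixels
#' are carried to a target year by keeping only the pixels whose six-band
#' spectral signatures are deemed unchanged under the Euclidean-distance
#' and spectral-angle criteria of `rule`. Retained samples are re-stamped
#' with `provenance = "migrated"` and the target year. Samples with nodata
#' in either year's composite are dropped and counted separately.
#'
#' @param training a `sample_points` data.frame (reference-year labels).
#' @param ref_composite,target_composite composites providing the six
#'   reflective bands on one grid (bare band names or `medoid_` layers);
#'   typically annual signature composites, see
#'   [annual_signature_composite()].
#' @param rule a [migration_rule()].
#' @param target_year year stamped on retained samples.
#' @return A list with `training` (the migrated `sample_points`) and
#'   `report`, a `migration_report` holding `n_input`, `n_retained`,
#'   `n_nodata`, per-class retention fractions, and the per-sample table of
#'   `ed`, `sad`, `kept`.
#' @export
migrate_training <- function(training, ref_composite, target_composite, rule =
                               migration_rule(), target_year = NA_integer_) {
  if (!nrow(training)) stop("empty training set", call. = FALSE)
  check_same_grid(ref_composite$grid, target_composite$grid, "composites")
  X <- signature_matrix(ref_composite, training$row, training$col)
  Y <- signature_matrix(target_composite, training$row, training$col)
  usable <- stats::complete.cases(X) & stats::complete.cases(Y)
  ed <- sad <- rep(NA_real_, nrow(training))
  kept <- rep(FALSE, nrow(training))
  if (any(usable)) {
    ed[usable] <- euclidean_distance(X[usable, , drop = FALSE],
                                     Y[usable, , drop = FALSE])
    sad[usable] <- spectral_angle(X[usable, , drop = FALSE],
                                  Y[usable, , drop = FALSE])
    kept[usable] <- rule_keep(rule, ed[usable], sad[usable])
  }
  out <- training[kept, , drop = FALSE]
  out$provenance <- rep("migrated", nrow(out))
  out$year <- rep(as.integer(target_year), nrow(out))
  per_class <- tapply(kept[usable], training$class_id[usable], mean)
  report <- structure(
    list(n_input = nrow(training), n_retained = sum(kept),
         n_nodata = sum(!usable),
         retention = sum(kept) / max(sum(usable), 1L),
         per_class_retention = per_class,
         samples = data.frame(row = training$row, col = training$col,
                              class_id = training$class_id,
                              ed = ed, sad = sad, kept = kept)),
    class = "migration_report")
  list(training = out, report = report)
}

#' @export
print.migration_report <- function(x, ...) {
  cat(sprintf("<migration_report> %d / %d retained (%.1f%%), %d nodata\n",
              x$n_retained, x$n_input, 100 * x$retention, x$n_nodata))
  invisible(x)
}

#' Annual six-band signature composite
#'
#' Averages the dry- and wet-season medoid bands into one annual six-band
#' signature stack (plain band-name layers), the spectral coordinates used
#' by [migrate_training()]. A pixel missing in one season falls back to the
#' other.
#'
#' @param dry,wet seasonal `lulc_composite`s with `medoid_<band>` layers.
#' @return An `lulc_composite` with the six reflective-band layers.
#' @export
annual_signature_composite <- function(dry, wet) {
  check_same_grid(dry$grid, wet$grid, "seasonal composites")
  layers <- lapply(REFLECTIVE_BANDS, function(b) {
    d <- composite_bands(dry)[[b]]
    w <- composite_bands(wet)[[b]]
    if (is.null(d) || is.null(w))
      stop("seasonal composites lack band ", b, call. = FALSE)
    out <- (d + w) / 2
    out[is.na(d)] <- w[is.na(d)]
    out[is.na(w)] <- d[is.na(w)]
    out
  })
  names(layers) <- REFLECTIVE_BANDS
  composite(layers, dry$grid)
}

#' Grid-search helper for migration thresholds
#'
#' Evaluates retention (and, when true labels for the target year are
#' supplied, label purity) over a grid of candidate thresholds, supporting
#' the trial-and-error threshold selection the migration model requires.
#'
#' @inheritParams migrate_training
#' @param ed_grid,sad_grid candidate thresholds.
#' @param truth optional `lulc_labels` for the target year, used to score
#'   retained-label purity.
#' @param ... further arguments passed to [migration_rule()].
#' @return data.frame with one row per threshold pair: `ed_threshold`,
#'   `sad_threshold`, `retention`, and `purity` (NA without `truth`).
#' @export
migration_threshold_search <- function(training, ref_composite,
                                       target_composite,
                                       ed_grid = c(0.02, 0.05, 0.1),
                                       sad_grid = c(0.5, 0.95),
                                       truth = NULL, ...) {
  grid <- expand.grid(ed_threshold = ed_grid, sad_threshold = sad_grid)
  grid$retention <- NA_real_; grid$purity <- NA_real_
  for (i in seq_len(nrow(grid))) {
    rule <- migration_rule(grid$ed_threshold[i], grid$sad_threshold[i], ...)
    res <- migrate_training(training, ref_composite, target_composite, rule)
    grid$retention[i] <- res$report$retention
    if (!is.null(truth) && nrow(res$training)) {
      tl <- truth$values[cbind(res$training$row + 1L, res$training$col + 1L)]
      grid$purity[i] <- mean(tl == res$training$class_id, na.rm = TRUE)
    }
  }
  grid
}
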