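#' Covariate collection
#'
#' One of the four per-season feature stacks the fusion classifier consumes
#' (`optical_dry`, `optical_wet`, `sar_dry`, `sar_wet`), optionally with
#' ancillary layers appended. Each collection is classified independently;
#' its class-probability raster is one factor of the fused posterior.
#'
#' @param id collection identifier.
#' @param layers named list of feature matrices on one grid (`NA` =
#'   nodata).
#' @param grid a [grid_spec()].
#' @return An object of class `covariate_collection`.
#' @export
covariate_collection <- function(id, layers, grid) {
  if (anyDuplicated(names(layers)))
    stop("duplicate feature names", call. = FALSE)
  check_layer_shapes(layers, grid, "feature")
  structure(list(id = id, layers = layers, grid = grid),
            class = "covariate_collection")
}

#' @export
print.covariate_collection <- function(x, ...) {
  cat(sprintf("<covariate_collection> '%s', %d features, %s\n",
              x$id, length(x$layers), format(x$grid)))
  invisible(x)
}

#' Flatten a collection into a feature matrix
#'
#' @param x a `covariate_collection` (or `lulc_composite`).
#' @return Numeric matrix, one row per pixel (column-major pixel order), one
#'   named column per feature.
#' @export
as_feature_matrix <- function(x) {
  out <- vapply(x$layers, as.vector,
                numeric(x$grid$n_rows * x$grid$n_cols))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(x$layers),
                                       dimnames = list(NULL, names(x$layers)))
  out
}

features_at <- function(x, rows, cols) {
  idx <- cbind(rows + 1L, cols + 1L)
  out <- vapply(x$layers, function(m) m[idx], numeric(length(rows)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(rows),
                                       dimnames = list(NULL, names(x$layers)))
  out
}

#' Random-forest settings
#'
#' Hyperparameters of the per-collection random forests. The defaults
#' follow the tuned values of the mapping framework: 200 trees and random
#' feature subsets of 8 per split (`max_features`, clamped to the feature
#' count after pruning); everything else stays at library defaults.
#'
#' @param num_trees number of trees (>= 1).
#' @param max_features features tried per split.
#' @param seed integer seed making fitting and prediction deterministic.
#' @return An object of class `rf_settings`.
#' @export
rf_settings <- function(num_trees = 200L, max_features = 8L, seed = 1L) {
  stopifnot(num_trees >= 1, max_features >= 1)
  structure(list(num_trees = as.integer(num_trees),
                 max_features = as.integer(max_features),
                 seed = as.integer(seed)),
            class = "rf_settings")
}

training_xy <- function(collection, training) {
  X <- features_at(collection, training$row, training$col)
  y <- training$class_id
  keep <- stats::complete.cases(X)
  if (!any(keep)) stop("no training pixel is valid in collection '",
                       collection$id, "'", call. = FALSE)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (any(!is.finite(X)))
    stop("non-finite feature values at training pixels", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training set has a single class", call. = FALSE)
  list(X = as.data.frame(X), y = y)
}

#' Prune features by cumulative importance
#'
#' Fits one forest on the training pixels, ranks features by impurity
#' importance, and keeps the smallest prefix whose cumulative share of
#' total importance reaches `retention`; at least one feature always
#' survives. Dropped names are recorded in the `dropped` attribute.
#'
#' @param collection a `covariate_collection`.
#' @param training a `sample_points` data.frame.
#' @param retention cumulative-importance fraction in (0, 1\]; default
#'   0.95.
#' @param settings an [rf_settings()].
#' @return The pruned `covariate_collection`.
#' @export
prune_features <- function(collection, training, retention = 0.95,
                           settings = rf_settings()) {
  stopifnot(retention > 0, retention <= 1)
  tr <- training_xy(collection, training)
  fit <- ranger::ranger(x = tr$X, y = factor(tr$y),
                        num.trees = settings$num_trees,
                        mtry = min(settings$max_features, ncol(tr$X)),
                        importance = "impurity",
                        seed = settings$seed, num.threads = 1)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  if (retention == 1) {
    keep <- names(imp)
  } else {
    share <- cumsum(imp) / sum(imp)
    keep <- names(imp)[seq_len(max(1L, which(share >= retention)[1]))]
  }
  dropped <- setdiff(names(collection$layers), keep)
  out <- covariate_collection(collection$id,
                              collection$layers[names(collection$layers)
                                                %in% keep],
                              collection$grid)
  attr(out, "dropped") <- dropped
  out
}

#' Fit one collection's random forest
#'
#' Fits a probability forest on the training pixels of one covariate
#' collection. Prediction emits per-class prior probability vectors;
#' fitting is deterministic given `settings$seed`.
#'
#' @inheritParams prune_features
#' @return An object of class `collection_model`.
#' @export
fit_collection_model <- function(collection, training,
                                 settings = rf_settings()) {
  tr <- training_xy(collection, training)
  class_ids <- sort(unique(tr$y))
  y <- factor(tr$y, levels = class_ids)
  fit <- ranger::ranger(x = tr$X, y = y,
                        num.trees = settings$num_trees,
                        mtry = min(settings$max_features, ncol(tr$X)),
                        probability = TRUE,
                        seed = settings$seed, num.threads = 1)
  structure(list(forest = fit, features = colnames(tr$X),
                 class_ids = class_ids, collection_id = collection$id,
                 settings = settings),
            class = "collection_model")
}

#' @export
print.collection_model <- function(x, ...) {
  cat(sprintf("<collection_model> '%s': %d trees, %d features, %d classes\n",
              x$collection_id, x$settings$num_trees, length(x$features),
              length(x$class_ids)))
  invisible(x)
}

#' Predict per-pixel prior probabilities
#'
#' Runs a fitted collection model over its collection's full grid. Pixels
#' with nodata in any model feature are flagged nodata *for this
#' collection*; the fusion step decides how missing collections enter the
#' posterior.
#'
#' @param model a `collection_model`.
#' @param collection a `covariate_collection` providing the model's
#'   features.
#' @return An object of class `prior_raster`: list with `p` (pixels x
#'   classes probability matrix, rows summing to 1 or all-`NA`),
#'   `class_ids`, `grid`.
#' @export
predict_priors <- function(model, collection) {
  miss <- setdiff(model$features, names(collection$layers))
  if (length(miss))
    stop("collection lacks model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as_feature_matrix(collection)[, model$features, drop = FALSE]
  ok <- stats::complete.cases(X)
  p <- matrix(NA_real_, nrow(X), length(model$class_ids),
              dimnames = list(NULL, model$class_ids))
  if (any(ok)) {
    pred <- stats::predict(model$forest, data = as.data.frame(X[ok, , drop = FALSE]),
                           num.threads = 1, seed = model$settings$seed)
    p[ok, ] <- pred$predictions[, as.character(model$class_ids), drop = FALSE]
  }
  structure(list(p = p, class_ids = model$class_ids, grid = collection$grid),
            class = "prior_raster")
}

#' Floor-adjust a prior probability
#'
#' The prior-probability adjustment `c * p + (1 - c) / N`: a convex pull of
#' each class prior toward the uniform distribution that imposes the floor
#' `(1 - c) / N > 0`. It exists because a single collection voting zero for
#' a class (often from noisy or gap-adjacent pixels) would otherwise
#' annihilate the across-collection probability product even when every
#' other collection votes for that class with certainty. With the defaults
#' `c = 0.7`, `N = 18`, the floor is `1/60`.
#'
#' @param p prior probability (vector/matrix allowed), in \[0, 1\].
#' @param c mixing constant in \[0, 1\]; `c = 1` is the identity.
#' @param N number of land-cover categories (>= 2).
#' @return Adjusted probabilities, in `[(1-c)/N, c + (1-c)/N]`.
#' @export
adjust_prior <- function(p, c = 0.7, N = 18L) {
  stopifnot(c >= 0, c <= 1, N >= 2)
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop("prior probabilities must lie in [0, 1]", call. = FALSE)
  c * p + (1 - c) / N
}

#' Fuse collection priors into a posterior
#'
#' The across-collection posterior: per pixel and class, the product of the
#' floor-adjusted priors `p'(C_k)` over the contributing collections. A
#' collection that is nodata at a pixel is skipped (contributes no factor)
#' rather than entering at its floor — entering floors for absent data
#' would pull gap pixels toward uniformity; the floor's purpose is
#' observed-but-zero priors, not missing observations. `missing = "floor"`
#' provides the strict alternative for comparison. Pixels where no
#' collection contributes are nodata.
#'
#' @param priors list of `prior_raster`s on one grid with one class order.
#' @param c mixing constant of [adjust_prior()].
#' @param N number of land-cover categories; defaults to the number of
#'   classes in the priors.
#' @param missing `"skip"` (default) or `"floor"`.
#' @param normalize if `TRUE`, posterior vectors are rescaled to sum to 1;
#'   by default the raw products are kept (argmax is unaffected).
#' @return An object of class `posterior_raster`: list with `p`,
#'   `n_contrib` (contributing collections per pixel), `class_ids`,
#'   `grid`.
#' @export
fuse_posterior <- function(priors, c = 0.7, N = NULL,
                           missing = c("skip", "floor"), normalize = FALSE) {
  missing <- match.arg(missing)
  stopifnot(length(priors) >= 1)
  ids <- priors[[1]]$class_ids
  grid <- priors[[1]]$grid
  for (pr in priors[-1]) {
    if (!identical(pr$class_ids, ids))
      stop("class-order mismatch between priors", call. = FALSE)
    check_same_grid(grid, pr$grid, "priors")
  }
  N <- N %||% length(ids)
  npix <- nrow(priors[[1]]$p)
  post <- matrix(1, npix, length(ids), dimnames = list(NULL, ids))
  n_contrib <- rep(0L, npix)
  floor_val <- adjust_prior(0, c, N)
  for (pr in priors) {
    ok <- stats::complete.cases(pr$p)
    n_contrib <- n_contrib + ok
    adj <- adjust_prior(pr$p[ok, , drop = FALSE], c, N)
    post[ok, ] <- post[ok, ] * adj
    if (missing == "floor" && any(!ok))
      post[!ok, ] <- post[!ok, ] * floor_val
  }
  none <- n_contrib == 0L
  post[none, ] <- NA_real_
  if (normalize) {
    s <- rowSums(post)
    post <- post / s
  }
  structure(list(p = post, n_contrib = n_contrib, class_ids = ids,
                 grid = grid),
            class = "posterior_raster")
}

#' Label pixels from a posterior
#'
#' Per-pixel argmax over the posterior class vector; exact ties resolve to
#' the lowest class id (deterministic), and nodata propagates.
#'
#' @param posterior a `posterior_raster`.
#' @param level taxonomy level recorded on the label raster.
#' @return An [label_raster()].
#' @export
classify_posterior <- function(posterior, level = 2L) {
  p <- posterior$p
  idx <- max.col(replace(p, is.na(p), -Inf), ties.method = "first")
  lab <- posterior$class_ids[idx]
  lab[!stats::complete.cases(p)] <- NA_integer_
  g <- posterior$grid
  label_raster(matrix(as.integer(lab), g$n_rows, g$n_cols), g, level = level)
}

#' Fit the multi-collection fusion classifier
#'
#' The framework's core classifier as one model object: an independent
#' probability random forest per covariate collection, fused at prediction
#' time by the floor-adjusted probability product ([adjust_prior()],
#' [fuse_posterior()]) and labeled by argmax. Optionally prunes each
#' collection to the `retention` cumulative-importance prefix first.
#'
#' @param collections named list of `covariate_collection`s (at most the
#'   four seasonal stacks, fewer when a sensor is unavailable).
#' @param training a `sample_points` data.frame; each sample must be valid
#'   in at least one collection.
#' @param c mixing constant of the prior adjustment.
#' @param N number of land-cover categories; defaults to the taxonomy size
#'   when supplied, else to the classes present.
#' @param taxonomy optional [lulc_taxonomy()] fixing `N` and the label
#'   level.
#' @param level taxonomy level of the training labels.
#' @param retention optional cumulative-importance retention in (0, 1\];
#'   `NULL` skips pruning.
#' @param settings an [rf_settings()].
#' @return An object of class `fusion_forest` with [predict.fusion_forest()]
#'   and print methods.
#' @export
fusion_forest <- function(collections, training, c = 0.7, N = NULL,
                          taxonomy = NULL, level = 2L, retention = NULL,
                          settings = rf_settings()) {
  stopifnot(length(collections) >= 1)
  if (is.null(names(collections)))
    names(collections) <- vapply(collections, `[[`, "", "id")
  if (!is.null(retention))
    collections <- lapply(collections, prune_features, training = training,
                          retention = retention, settings = settings)
  models <- lapply(collections, fit_collection_model, training = training,
                   settings = settings)
  ids <- models[[1]]$class_ids
  N <- N %||% (if (!is.null(taxonomy)) {
    if (level == 1L) nrow(taxonomy$level1) else taxonomy$n
  } else length(ids))
  structure(list(models = models, features = lapply(models, `[[`, "features"),
                 class_ids = ids, c = c, N = N, level = as.integer(level),
                 settings = settings),
            class = "fusion_forest")
}

#' @export
print.fusion_forest <- function(x, ...) {
  cat(sprintf("<fusion_forest> %d collections, %d classes, c = %g, N = %d\n",
              length(x$models), length(x$class_ids), x$c, x$N))
  for (m in x$models) {
    cat("  "); print(m)
  }
  invisible(x)
}

#' Predict from a fusion classifier
#'
#' @param object a [fusion_forest()].
#' @param collections named list of `covariate_collection`s matching the
#'   fitted ones (a subset is allowed, e.g. optical-only years).
#' @param type `"labels"` for an [label_raster()], `"posterior"` for the
#'   fused `posterior_raster`, `"priors"` for the per-collection prior
#'   rasters.
#' @param missing how nodata collections enter the product; see
#'   [fuse_posterior()].
#' @param ... unused.
#' @return See `type`.
#' @export
predict.fusion_forest <- function(object, collections,
                                  type = c("labels", "posterior", "priors"),
                                  missing = "skip", ...) {
  type <- match.arg(type)
  use <- intersect(names(object$models), names(collections))
  if (!length(use)) stop("no fitted collection matches the input", call. = FALSE)
  priors <- lapply(use, function(nm)
    predict_priors(object$models[[nm]], collections[[nm]]))
  names(priors) <- use
  if (type == "priors") return(priors)
  post <- fuse_posterior(priors, c = object$c, N = object$N,
                         missing = missing)
  if (type == "posterior") return(post)
  classify_posterior(post, level = object$level)
}
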