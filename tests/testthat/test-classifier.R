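test_that("prior adjustment matches the closed form and its bounds", {
  expect_equal(adjust_prior(0, 0.7, 18), 0.3 / 18)
  expect_equal(adjust_prior(0, 0.7, 18), 0.016667, tolerance = 1e-4)
  expect_equal(adjust_prior(1, 0.7, 18), 0.7 + 0.3 / 18)
  expect_equal(adjust_prior(1, 0.7, 18), 0.716667, tolerance = 1e-4)
  expect_equal(adjust_prior(0.42, 1, 18), 0.42) # c = 1 is the identity
  # floor guarantee: with c = 0.7, N = 18 every adjusted prior >= 1/60
  p <- seq(0, 1, 0.05)
  expect_true(all(adjust_prior(p, 0.7, 18) >= 1 / 60 - 1e-15))
  expect_true(all(adjust_prior(p, 0.7, 18) <= 0.7 + 1 / 60 + 1e-15))
  expect_error(adjust_prior(1.2, 0.7, 18), "0, 1")
})

fake_prior <- function(p_rows, grid, ids = seq_len(ncol(p_rows))) {
  structure(list(p = `colnames<-`(p_rows, ids), class_ids = ids,
                 grid = grid), class = "prior_raster")
}

test_that("posterior fusion reproduces the hand-computed product values", {
  g <- grid_spec(1, 1)
  onehot <- matrix(c(1, rep(0, 17)), 1, 18)
  priors <- lapply(1:4, function(i) fake_prior(onehot, g, 1:18))
  post <- fuse_posterior(priors, c = 0.7, N = 18)
  expect_equal(unname(post$p[1, 1]), (0.7 + 0.3 / 18)^4)
  expect_equal(unname(post$p[1, 1]), 0.263796, tolerance = 1e-4)
  expect_equal(unname(post$p[1, 2]), (0.3 / 18)^4)
  expect_equal(unname(post$p[1, 2]), 7.716e-8, tolerance = 1e-3)
  # three unanimous votes against one zero: the floor keeps the class on top
  zero <- matrix(c(0, 1, rep(0, 16)), 1, 18)
  mixed <- fuse_posterior(c(priors[1:3], list(fake_prior(zero, g, 1:18))),
                          c = 0.7, N = 18)
  expect_equal(unname(mixed$p[1, 1]), (0.7 + 0.3 / 18)^3 * (0.3 / 18),
               tolerance = 1e-12)
  expect_equal(unname(mixed$p[1, 1]), 6.134e-3, tolerance = 1e-3)
  uniform_post <- (0.7 / 18 + 0.3 / 18)^4
  expect_gt(unname(mixed$p[1, 1]), uniform_post)
  expect_identical(unname(which.max(mixed$p[1, ])), 1L)
})

test_that("single collection with c = 1 passes priors through unchanged", {
  g <- grid_spec(1, 2)
  p <- matrix(c(0.6, 0.3, 0.1, 0.2, 0.5, 0.3), 2, 3, byrow = TRUE)
  post <- fuse_posterior(list(fake_prior(p, g, 1:3)), c = 1, N = 3)
  expect_equal(unname(post$p), unname(p))
})

test_that("nodata collections are skipped, not floored, by default", {
  g <- grid_spec(1, 1)
  good <- fake_prior(matrix(c(0.9, 0.1), 1, 2), g, 1:2)
  gap <- fake_prior(matrix(NA_real_, 1, 2), g, 1:2)
  post <- fuse_posterior(list(good, gap), c = 0.7, N = 2)
  expect_identical(post$n_contrib, 1L)
  expect_equal(unname(post$p[1, 1]), adjust_prior(0.9, 0.7, 2))
  # strict mode floors the missing collection instead
  strict <- fuse_posterior(list(good, gap), c = 0.7, N = 2,
                           missing = "floor")
  expect_equal(unname(strict$p[1, 1]), adjust_prior(0.9, 0.7, 2) * 0.15)
  # a pixel with zero contributing collections is nodata
  none <- fuse_posterior(list(gap), c = 0.7, N = 2)
  expect_true(all(is.na(none$p)))
  expect_error(fuse_posterior(list(good, fake_prior(matrix(0.5, 1, 3),
                                                    g, 1:3))),
               "class-order")
})

test_that("fusion is invariant to collection order and argmax to scaling", {
  set.seed(41)
  g <- grid_spec(2, 2)
  priors <- lapply(1:4, function(i) {
    p <- matrix(runif(4 * 5), 4, 5)
    fake_prior(p / rowSums(p), g, 1:5)
  })
  a <- fuse_posterior(priors)
  b <- fuse_posterior(rev(priors))
  expect_equal(a$p, b$p)
  lab1 <- classify_posterior(a)
  scaled <- a; scaled$p <- a$p * 17.3
  expect_identical(classify_posterior(scaled)$values, lab1$values)
  # exact ties resolve to the lowest class id
  tie <- fake_prior(matrix(c(0.4, 0.4, 0.2), 1, 3), grid_spec(1, 1), 1:3)
  post <- fuse_posterior(list(tie), c = 1)
  expect_identical(classify_posterior(post)$values[1, 1], 1L)
})

test_that("feature pruning keeps the informative feature and honors retention = 1", {
  set.seed(42)
  g <- grid_spec(20, 20)
  npix <- 400
  truth <- matrix(rep(1:2, length.out = npix), 20, 20)
  layers <- c(list(signal = matrix(ifelse(truth == 1, 0, 1) +
                                     rnorm(npix, 0, 0.01), 20, 20)),
              lapply(stats::setNames(1:9, paste0("noise", 1:9)),
                     function(i) matrix(rnorm(npix), 20, 20)))
  coll <- covariate_collection("optical_dry", layers, g)
  training <- sample_training(label_raster(truth, g), 60, seed = 1)
  pruned <- prune_features(coll, training, retention = 0.5)
  expect_true("signal" %in% names(pruned$layers))
  expect_lt(length(pruned$layers), length(layers))
  expect_true(all(attr(pruned, "dropped") %in% paste0("noise", 1:9)))
  full <- prune_features(coll, training, retention = 1.0)
  expect_identical(names(full$layers), names(layers))
  expect_error(prune_features(coll, training[training$class_id == 1, ],
                              retention = 0.5), "single class")
})

test_that("collection models separate separable classes and are seed-deterministic", {
  fx <- separable_problem()
  m1 <- fit_collection_model(fx$collection, fx$training,
                             rf_settings(num_trees = 100, seed = 7))
  pr1 <- predict_priors(m1, fx$collection)
  # training-set accuracy is perfect on a separable problem
  idx <- fx$training$row + 1 + fx$training$col * fx$grid$n_rows
  lab <- classify_posterior(fuse_posterior(list(pr1), c = 1))
  expect_equal(mean(lab$values[cbind(fx$training$row + 1,
                                     fx$training$col + 1)] ==
                      fx$training$class_id), 1)
  # probabilities sum to one at every valid pixel
  expect_equal(unname(rowSums(pr1$p)), rep(1, nrow(pr1$p)))
  # same data, same seed: identical priors
  m2 <- fit_collection_model(fx$collection, fx$training,
                             rf_settings(num_trees = 100, seed = 7))
  expect_equal(predict_priors(m2, fx$collection)$p, pr1$p)
  expect_error(fit_collection_model(fx$collection,
                                    fx$training[fx$training$class_id == 1, ]),
               "single class")
})

test_that("nodata features flag nodata priors and pure clusters score high", {
  fx <- separable_problem()
  coll <- fx$collection
  coll$layers$sig[1, 1] <- NA
  m <- fit_collection_model(coll, fx$training, rf_settings(seed = 1))
  pr <- predict_priors(m, coll)
  expect_true(all(is.na(pr$p[1, ])))
  ok <- stats::complete.cases(pr$p)
  # pixels sitting on the pure training clusters get confident priors
  expect_gt(min(apply(pr$p[ok, ], 1, max)), 0.9)
  expect_error(predict_priors(m, covariate_collection("x", list(
    other = coll$layers$sig), coll$grid)), "feature")
})

test_that("with one collection and c = 1 fused labels equal the forest argmax", {
  fx <- separable_problem()
  m <- fit_collection_model(fx$collection, fx$training, rf_settings(seed = 2))
  pr <- predict_priors(m, fx$collection)
  fused <- classify_posterior(fuse_posterior(list(pr), c = 1))
  direct <- pr$class_ids[max.col(pr$p, ties.method = "first")]
  expect_identical(as.vector(fused$values), as.integer(direct))
})

test_that("the fusion_forest object wraps fit, predict, and print", {
  fx <- separable_problem()
  coll2 <- fx$collection; coll2$id <- "optical_wet"
  colls <- list(optical_dry = fx$collection, optical_wet = coll2)
  ff <- fusion_forest(colls, fx$training, c = 0.7,
                      settings = rf_settings(num_trees = 50, seed = 3))
  expect_s3_class(ff, "fusion_forest")
  expect_output(print(ff), "fusion_forest")
  lab <- predict(ff, colls)
  acc <- mean(lab$values == fx$truth$values, na.rm = TRUE)
  expect_gt(acc, 0.99)
  post <- predict(ff, colls, type = "posterior")
  expect_identical(post$n_contrib, rep(2L, 400))
  # a subset of collections still predicts (optical-only mode)
  lab1 <- predict(ff, colls["optical_dry"])
  expect_gt(mean(lab1$values == fx$truth$values, na.rm = TRUE), 0.99)
})
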