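test_that("Euclidean distance and spectral angle match closed forms", {
  x <- c(0.2, 0.3, 0.1, 0.4, 0.2, 0.1)
  expect_equal(euclidean_distance(x, x), 0)
  expect_equal(euclidean_distance(x, x + c(0.03, 0.04, 0, 0, 0, 0)), 0.05)
  expect_equal(euclidean_distance(rep(0, 6), c(1, 0, 0, 0, 0, 0)), 1)
  expect_equal(spectral_angle(x, 2 * x), 0)
  expect_equal(spectral_angle(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0)),
               pi / 2)
  expect_equal(spectral_angle(c(1, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0)),
               pi / 4)
  expect_error(euclidean_distance(x, x[1:3]), "length mismatch")
  expect_error(spectral_angle(rep(0, 6), x), "zero-norm")
  expect_error(euclidean_distance(c(x[-1], NA), x), "non-finite")
})

mig_fixture <- function(shift = NULL, n = 10, seed = 5) {
  set.seed(seed)
  g <- grid_spec(5, 5)
  ref_layers <- lapply(REFLECTIVE_BANDS, function(b)
    matrix(runif(25, 0.1, 0.5), 5, 5))
  names(ref_layers) <- REFLECTIVE_BANDS
  tgt_layers <- ref_layers
  if (!is.null(shift))
    for (i in seq_along(REFLECTIVE_BANDS))
      tgt_layers[[i]] <- tgt_layers[[i]] + shift[i]
  training <- structure(
    data.frame(row = rep(0:4, 5)[1:n], col = rep(0:4, each = 5)[1:n],
               class_id = rep(1:2, length.out = n), level = 2L,
               year = 2020L, provenance = "ground"),
    class = c("sample_points", "data.frame"))
  list(training = training, ref = composite(ref_layers, g),
       tgt = composite(tgt_layers, g))
}

test_that("identical composites migrate every sample with zero distances", {
  fx <- mig_fixture()
  res <- migrate_training(fx$training, fx$ref, fx$tgt,
                          migration_rule(), target_year = 1995)
  expect_identical(res$report$n_retained, nrow(fx$training))
  expect_true(all(res$report$samples$ed == 0))
  expect_true(all(res$report$samples$sad < 1e-6))
  expect_true(all(res$training$provenance == "migrated"))
  expect_true(all(res$training$year == 1995L))
})

test_that("the ED boundary case is retained under the inclusive convention", {
  fx <- mig_fixture(shift = c(0.03, 0.04, 0, 0, 0, 0))
  res <- migrate_training(fx$training, fx$ref, fx$tgt, migration_rule())
  expect_equal(unique(round(res$report$samples$ed, 12)), 0.05)
  expect_identical(res$report$n_retained, nrow(fx$training))
  # just past the threshold every sample drops
  fx2 <- mig_fixture(shift = c(0.031, 0.04, 0, 0, 0, 0))
  res2 <- migrate_training(fx2$training, fx2$ref, fx2$tgt, migration_rule())
  expect_identical(res2$report$n_retained, 0L)
})

test_that("an orthogonal replacement spectrum is dropped under any interpretation", {
  fx <- mig_fixture()
  # replace target spectrum at one training pixel by an orthogonal vector
  r <- fx$training$row[1] + 1; cl <- fx$training$col[1] + 1
  for (b in REFLECTIVE_BANDS) fx$tgt$layers[[b]][r, cl] <- 0
  fx$tgt$layers[["Bblue"]][r, cl] <- 9 # ref has tiny blue weight only
  for (interp in c("angle_radians", "cosine_similarity")) {
    res <- migrate_training(fx$training, fx$ref, fx$tgt,
                            migration_rule(sad_interpretation = interp))
    expect_false(res$report$samples$kept[1])
  }
})

test_that("nodata pixels are dropped and counted separately", {
  fx <- mig_fixture()
  fx$tgt$layers$Bnir[1, 1] <- NA # training sample at (0,0)
  res <- migrate_training(fx$training, fx$ref, fx$tgt, migration_rule())
  expect_identical(res$report$n_nodata, 1L)
  expect_identical(res$report$n_retained, nrow(fx$training) - 1L)
})

test_that("retention is monotone in both thresholds", {
  set.seed(31)
  fx <- mig_fixture(shift = NULL)
  # perturb the target randomly so distances spread around the thresholds
  for (b in REFLECTIVE_BANDS)
    fx$tgt$layers[[b]] <- fx$tgt$layers[[b]] + rnorm(25, 0, 0.03)
  kept <- vapply(c(0.01, 0.03, 0.05, 0.1, 0.3), function(ed) {
    migrate_training(fx$training, fx$ref, fx$tgt,
                     migration_rule(ed_threshold = ed))$report$n_retained
  }, integer(1))
  expect_true(all(diff(kept) >= 0))
  kept_sad <- vapply(c(0.05, 0.2, 0.5, 1), function(sad) {
    migrate_training(fx$training, fx$ref, fx$tgt,
                     migration_rule(ed_threshold = 0.5,
                                    sad_threshold = sad))$report$n_retained
  }, integer(1))
  expect_true(all(diff(kept_sad) >= 0))
})

test_that("SAD decisions are invariant to a common brightness rescaling", {
  set.seed(32)
  fx <- mig_fixture()
  for (b in REFLECTIVE_BANDS)
    fx$tgt$layers[[b]] <- fx$tgt$layers[[b]] * (1 + rnorm(25, 0, 0.1))
  rule <- migration_rule(ed_threshold = 1e6, sad_threshold = 0.2) # SAD only
  base <- migrate_training(fx$training, fx$ref, fx$tgt, rule)
  lam <- 3.7
  fx$ref$layers <- lapply(fx$ref$layers, `*`, lam)
  fx$tgt$layers <- lapply(fx$tgt$layers, `*`, lam)
  scaled <- migrate_training(fx$training, fx$ref, fx$tgt, rule)
  expect_identical(scaled$report$samples$kept, base$report$samples$kept)
  expect_equal(scaled$report$samples$sad, base$report$samples$sad)
})

test_that("migration recovers pure labels when a known fraction of pixels change class", {
  # synthetic two-year composites: class means >= 5 noise SD apart, 20% of
  # training pixels change class in the target year
  cfg <- pipeline_config(years = c(2015, 2020), ref_year = 2020,
                         grid = grid_spec(48, 48), n_classes = 4L,
                         noise_sd = 0.02, separation = 5,
                         cloud_fraction = 0, scenes_per_season = 3,
                         script = change_script(2015, from = 1, to = 2,
                                                fraction = 0.3),
                         seed = 99)
  data <- simulate_dataset(cfg)
  truth_ref <- data$truth[["2020"]]
  training <- sample_training(truth_ref, 80, year = 2020, seed = 3)
  sig <- function(y) {
    sc <- data$scenes[[as.character(y)]]$optical
    annual_signature_composite(medoid_composite(sc$dry),
                               medoid_composite(sc$wet))
  }
  res <- migrate_training(training, sig(2020), sig(2015),
                          migration_rule(), target_year = 2015)
  kept <- res$training
  expect_gt(nrow(kept), 0)
  tl <- data$truth[["2015"]]$values[cbind(kept$row + 1, kept$col + 1)]
  expect_gte(mean(tl == kept$class_id), 0.95)
})

test_that("the threshold grid-search helper reports retention and purity", {
  fx <- mig_fixture()
  g <- fx$ref$grid
  truth <- label_raster(matrix(rep(1:2, length.out = 25), 5, 5), g, 2L)
  out <- migration_threshold_search(fx$training, fx$ref, fx$tgt,
                                    ed_grid = c(0.01, 0.1),
                                    sad_grid = 0.95, truth = truth)
  expect_identical(nrow(out), 2L)
  expect_true(all(out$retention == 1)) # identical composites
})
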