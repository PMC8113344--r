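test_that("season assignment follows the dry/wet month rule with the wet-year boundary", {
  sd <- season_definition()
  expect_equal(assign_season(as.Date("2020-05-15"), sd),
               data.frame(season = "dry", year = 2020L))
  expect_equal(assign_season(as.Date("2020-01-20"), sd),
               data.frame(season = "wet", year = 2019L))
  # 12 monthly scenes of one year split 6 dry / 6 wet
  months <- sprintf("2020-%02d-15", 1:12)
  a <- assign_season(as.Date(months), sd)
  expect_identical(sum(a$season == "dry"), 6L)
  expect_identical(sum(a$season == "wet"), 6L)
  scenes <- band_stack(rep(list(matrix(0.1, 1, 1)), 12),
                       dates = as.Date(months))
  buckets <- partition_by_season(scenes)
  expect_setequal(names(buckets), c("wet_2019", "dry_2020", "wet_2020"))
  expect_identical(length(buckets$dry_2020), 6L)
  expect_error(season_definition(1:5, 7:12), "partition")
})

test_that("medoid composite minimizes total distance and is an input member", {
  vals <- list(matrix(0.1, 1, 1), matrix(0.2, 1, 1), matrix(0.9, 1, 1))
  mc <- medoid_composite(band_stack(vals), bands = "Bblue")
  expect_equal(mc$layers$medoid_Bblue[1, 1], 0.2)
  # a single scene is its own medoid
  one <- medoid_composite(band_stack(vals[1]), bands = "Bblue")
  expect_equal(one$layers$medoid_Bblue[1, 1], 0.1)
  expect_error(medoid_composite(list()), "empty")
})

test_that("medoid membership and permutation invariance hold exhaustively on small stacks", {
  set.seed(11)
  g <- grid_spec(4, 4)
  for (n in 2:5) {
    scenes <- lapply(seq_len(n), function(i)
      noisy_scene(g, means = runif(6, 0.1, 0.5), sd = 0.05, seed = 100 + i))
    mc <- medoid_composite(scenes)
    # membership: each pixel's band vector equals one input observation
    for (r in 1:4) for (cl in 1:4) {
      out <- vapply(REFLECTIVE_BANDS,
                    function(b) mc$layers[[paste0("medoid_", b)]][r, cl], 0)
      obs <- vapply(scenes, function(s)
        all(abs(vapply(REFLECTIVE_BANDS, function(b) s$bands[[b]][r, cl], 0)
                - out) < 1e-12), TRUE)
      expect_true(any(obs))
    }
    # brute-force oracle at one pixel: minimize summed pairwise distance
    X <- t(vapply(scenes, function(s)
      vapply(REFLECTIVE_BANDS, function(b) s$bands[[b]][2, 3], 0),
      numeric(6)))
    sums <- rowSums(as.matrix(dist(X)))
    # ties (exact in two-scene stacks) resolve lexicographically on bands
    ord <- do.call(order, c(list(sums), lapply(1:6, function(j) X[, j])))
    expect_equal(unname(vapply(REFLECTIVE_BANDS,
                               function(b) mc$layers[[paste0("medoid_", b)]][2, 3], 0)),
                 unname(X[ord[1], ]))
    # permutation invariance
    mc2 <- medoid_composite(rev(scenes))
    for (nm in names(mc$layers)) expect_equal(mc2$layers[[nm]], mc$layers[[nm]])
  }
})

test_that("adding a fully-masked scene changes no composite value", {
  g <- grid_spec(3, 3)
  scenes <- lapply(1:3, function(i)
    noisy_scene(g, means = rep(0.3, 6), sd = 0.05, seed = i))
  blank <- noisy_scene(g, means = rep(0.9, 6), sd = 0, seed = 9)
  blank$mask[] <- MASK_CODES[["cloud"]]
  for (fn in list(medoid_composite, stddev_composite)) {
    a <- fn(scenes); b <- fn(c(scenes, list(blank)))
    for (nm in names(a$layers)) expect_equal(b$layers[[nm]], a$layers[[nm]])
  }
})

test_that("percentile medoid matches the nearest-rank oracle on known stacks", {
  vals <- lapply(seq(0.1, 0.5, 0.1), matrix, nrow = 1, ncol = 1)
  scenes <- band_stack(vals)
  expect_equal(percentile_medoid_composite(scenes, bands = "Bblue",
                                           q = 20)$layers$p20_Bblue[1, 1], 0.2)
  expect_equal(percentile_medoid_composite(scenes, bands = "Bblue",
                                           q = 80)$layers$p80_Bblue[1, 1], 0.4)
  # identical observations: any observation is acceptable (all equal)
  same <- band_stack(rep(list(matrix(0.3, 1, 1)), 4))
  expect_equal(percentile_medoid_composite(same, bands = "Bblue",
                                           q = 20)$layers$p20_Bblue[1, 1], 0.3)
  # <= 2 valid observations fall back to the plain medoid
  two <- band_stack(list(matrix(0.1, 1, 1), matrix(0.4, 1, 1)))
  p <- percentile_medoid_composite(two, bands = "Bblue", q = 80)
  expect_true(p$layers$p80_Bblue[1, 1] %in% c(0.1, 0.4))
  expect_error(percentile_medoid_composite(scenes, q = 0), "0, 100")
})

test_that("standard deviation composite is population-form with small-n rules", {
  g <- grid_spec(1, 1)
  mk <- function(v) band_stack(lapply(v, matrix, nrow = 1, ncol = 1))
  expect_equal(stddev_composite(mk(c(0.1, 0.3)),
                                bands = "Bblue")$layers$std_Bblue[1, 1], 0.1)
  expect_equal(stddev_composite(mk(c(0.1, 0.2, 0.3)),
                                bands = "Bblue")$layers$std_Bblue[1, 1],
               sqrt(2 / 3) * 0.1)
  expect_equal(stddev_composite(mk(rep(0.4, 5)),
                                bands = "Bblue")$layers$std_Bblue[1, 1], 0)
  expect_equal(stddev_composite(mk(0.2),
                                bands = "Bblue")$layers$std_Bblue[1, 1], 0)
})

test_that("SAR seasonal covariates compute means and the normalized polarization difference", {
  g <- grid_spec(1, 1)
  s1 <- sar_scene(matrix(-10, 1, 1), matrix(-16, 1, 1), "2020-06-01", g)
  cov <- sar_seasonal_covariates(list(s1))
  expect_equal(cov$layers$nd_VHVV[1, 1], (-16 - -10) / (-16 + -10))
  expect_equal(cov$layers$nd_VHVV[1, 1], 0.23077, tolerance = 1e-4)
  # VH = VV gives 0
  s2 <- sar_scene(matrix(-12, 1, 1), matrix(-12, 1, 1), "2020-06-01", g)
  expect_equal(sar_seasonal_covariates(list(s2))$layers$nd_VHVV[1, 1], 0)
  # two-scene mean
  s3 <- sar_scene(matrix(-8, 1, 1), matrix(-15, 1, 1), "2020-06-10", g)
  s4 <- sar_scene(matrix(-12, 1, 1), matrix(-17, 1, 1), "2020-07-10", g)
  expect_equal(sar_seasonal_covariates(list(s3, s4))$layers$mean_VV[1, 1], -10)
  # near-zero denominator is nodata
  s5 <- sar_scene(matrix(-5, 1, 1), matrix(5, 1, 1), "2020-06-01", g)
  expect_warning(cov5 <- sar_seasonal_covariates(list(s5)), NA)
  expect_true(is.na(cov5$layers$nd_VHVV[1, 1]))
  # orbits stay separate layers
  s6 <- sar_scene(matrix(-9, 1, 1), matrix(-14, 1, 1), "2020-06-01", g,
                  orbit = "descending")
  both <- sar_seasonal_covariates(list(s1, s6))
  expect_setequal(names(both$layers),
                  c("mean_VV_asc", "mean_VH_asc", "nd_VHVV_asc",
                    "mean_VV_desc", "mean_VH_desc", "nd_VHVV_desc"))
})

test_that("Lee filter leaves constants alone, is identity at zero noise, and damps spikes", {
  g <- grid_spec(5, 5)
  const <- sar_scene(matrix(-10, 5, 5), matrix(-15, 5, 5), "2020-06-01", g)
  f <- lee_filter(const, window = 3)
  expect_equal(f$vv, const$vv)
  spike <- matrix(-12, 5, 5); spike[3, 3] <- 0
  s <- sar_scene(spike, spike, "2020-06-01", g)
  # noise_var -> 0 makes W -> 1: output equals input
  f0 <- lee_filter(s, window = 3, noise_var = 1e-12)
  expect_equal(f0$vv, s$vv, tolerance = 1e-6)
  # with real noise estimate the spike amplitude strictly shrinks
  f1 <- lee_filter(s, window = 3)
  bg <- -12
  expect_lt(abs(f1$vv[3, 3] - bg), abs(s$vv[3, 3] - bg))
  expect_error(lee_filter(s, window = 4), "odd")
})

test_that("terrain covariates follow Horn's method with the stated aspect convention", {
  g <- grid_spec(9, 9, pixel_size = 30)
  flat <- matrix(100, 9, 9)
  tc <- terrain_covariates(flat, g)
  expect_true(all(tc$layers$slope == 0))
  expect_true(all(is.na(tc$layers$aspect)))
  # plane rising 1 m per 30 m eastward: slope = atan(1/30) everywhere interior
  plane <- matrix(rep(0:8, each = 9), 9, 9) # value = col index, rises east
  tcp <- terrain_covariates(plane * 1, g)   # 1 m per pixel = 1 m per 30 m
  expect_equal(tcp$layers$slope[5, 5], atan(1 / 30) * 180 / pi,
               tolerance = 1e-6)
  expect_equal(tcp$layers$slope[5, 5], 1.9091, tolerance = 1e-3)
  # down-slope of an east-rising plane faces west (270 degrees)
  expect_equal(tcp$layers$aspect[5, 5], 270)
  # plane rising southward (rows increase south): down-slope faces north (0)
  north <- matrix(rep(0:8, times = 9), 9, 9)
  tcn <- terrain_covariates(north * 1, g)
  expect_equal(tcn$layers$aspect[5, 5], 0)
  expect_error(terrain_covariates(matrix(1, 2, 2), grid_spec(2, 2)), "3 x 3")
})
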