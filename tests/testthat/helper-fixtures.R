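# Small in-code fixtures shared across test files.

# one-pixel optical scene with the six reflective bands set to `refl`
# (recycled) and optional thermal
px_scene <- function(refl, date = "2020-06-15", grid = grid_spec(1, 1),
                     tir = NULL, sensor = "OLI") {
  vals <- rep(refl, length.out = 6)
  bands <- lapply(vals, function(v) matrix(v, grid$n_rows, grid$n_cols))
  names(bands) <- REFLECTIVE_BANDS
  if (!is.null(tir)) bands$Btir <- matrix(tir, grid$n_rows, grid$n_cols)
  scene(bands, date = date, grid = grid, sensor = sensor)
}

# n-scene single-band stacks on an r x c grid from a list of value matrices
band_stack <- function(values, band = "Bblue", grid = NULL,
                       dates = NULL) {
  grid <- grid %||% grid_spec(nrow(values[[1]]), ncol(values[[1]]))
  dates <- dates %||% as.Date("2020-06-01") + seq_along(values)
  lapply(seq_along(values), function(i) {
    b <- list(values[[i]]); names(b) <- band
    scene(b, date = dates[i], grid = grid)
  })
}

# deterministic small multiband scene with per-band constants + noise
noisy_scene <- function(grid, means, sd = 0, seed = 1, date = "2020-06-15") {
  set.seed(seed)
  bands <- lapply(seq_len(6), function(i)
    matrix(means[i] + stats::rnorm(grid$n_rows * grid$n_cols, 0, sd),
           grid$n_rows, grid$n_cols))
  names(bands) <- REFLECTIVE_BANDS
  scene(bands, date = date, grid = grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny two-collection separable classification problem
separable_problem <- function(n_per_class = 40, grid = grid_spec(20, 20),
                              seed = 7) {
  set.seed(seed)
  npix <- grid$n_rows * grid$n_cols
  truth <- matrix(rep(1:2, length.out = npix), grid$n_rows, grid$n_cols)
  f1 <- matrix(ifelse(truth == 1, 0, 1) + rnorm(npix, 0, 0.01),
               grid$n_rows, grid$n_cols)
  f2 <- matrix(rnorm(npix), grid$n_rows, grid$n_cols)
  coll <- covariate_collection("optical_dry",
                               list(sig = f1, noise = f2), grid)
  labels <- label_raster(truth, grid)
  training <- sample_training(labels, n_per_class, seed = seed)
  list(collection = coll, truth = labels, training = training, grid = grid)
}
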