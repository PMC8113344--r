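#' Build the four covariate collections for one year
#'
#' Reduces a year's seasonal scene lists into the classifier's feature
#' stacks: per optical season the medoid, standard-deviation, and 20th/80th
#' percentile-medoid band composites plus spectral indices and band ratios
#' on the medoid bands; per SAR season the Lee-filtered seasonal means and
#' polarization difference. Ancillary layers (e.g. terrain) are appended to
#' every collection.
#'
#' @param optical list with `dry` and `wet` optical scene lists (either may
#'   be empty or `NULL`).
#' @param sar list with `dry` and `wet` SAR scene lists, or `NULL` for
#'   optical-only years.
#' @param indices index names appended from the medoid bands; see
#'   [compute_all_indices()].
#' @param ancillary optional `lulc_composite` of ancillary layers.
#' @param lee_window Lee filter window (odd); `0` disables filtering.
#' @return Named list of [covariate_collection()]s among `optical_dry`,
#'   `optical_wet`, `sar_dry`, `sar_wet`.
#' @export
make_covariate_collections <- function(optical, sar = NULL,
                                       indices = c(SPECTRAL_INDICES,
                                                   BAND_RATIOS),
                                       ancillary = NULL, lee_window = 5L) {
  out <- list()
  add_ancillary <- function(layers) {
    if (is.null(ancillary)) layers else c(layers, ancillary$layers)
  }
  for (season in c("dry", "wet")) {
    osc <- optical[[season]]
    if (length(osc)) {
      has_tir <- "Btir" %in% names(osc[[1]]$bands)
      bands <- if (has_tir) OPTICAL_BANDS else REFLECTIVE_BANDS
      med <- medoid_composite(osc, bands = bands)
      med$season <- season
      idx_names <- if (has_tir) indices else setdiff(indices, "NDBaI")
      med <- compute_all_indices(med, names = idx_names)
      std <- stddev_composite(osc, bands = REFLECTIVE_BANDS)
      p20 <- percentile_medoid_composite(osc, bands = REFLECTIVE_BANDS, q = 20)
      p80 <- percentile_medoid_composite(osc, bands = REFLECTIVE_BANDS, q = 80)
      layers <- c(med$layers, std$layers, p20$layers, p80$layers)
      out[[paste0("optical_", season)]] <-
        covariate_collection(paste0("optical_", season),
                             add_ancillary(layers), med$grid)
    }
    ssc <- sar[[season]]
    if (length(ssc)) {
      if (lee_window >= 3L) ssc <- lapply(ssc, lee_filter, window = lee_window)
      cov <- sar_seasonal_covariates(ssc)
      out[[paste0("sar_", season)]] <-
        covariate_collection(paste0("sar_", season),
                             add_ancillary(cov$layers), cov$grid)
    }
  }
  if (!length(out)) stop("no scenes supplied", call. = FALSE)
  out
}

#' Pipeline configuration
#'
#' One object holding every knob of a simulated multi-year mapping run:
#' study years, synthetic-scene conditions, migration rule, forest
#' settings, and fusion constants. Defaults are the package's reference
#' study conditions: 6 classes at 5-SD spectral separation, a 96 x 96 grid
#' of 30 m pixels, 3 scenes per season, 20% cloud, 200 training and 100
#' held-out validation pixels per class, and the published classifier
#' constants (`c = 0.7`, 200 trees, `max_features = 8`).
#'
#' @param years ascending simulated years.
#' @param ref_year reference year whose training samples are migrated to
#'   the others; defaults to the last year.
#' @param grid a [grid_spec()].
#' @param n_classes number of level-2 classes simulated.
#' @param separation class-mean separation in noise-SD units.
#' @param noise_sd optical band noise SD.
#' @param scenes_per_season scenes per season and sensor.
#' @param cloud_fraction expected optical cloud fraction.
#' @param n_training_per_class,n_validation_per_class sample sizes.
#' @param rule a [migration_rule()].
#' @param settings an [rf_settings()].
#' @param c,retention fusion constant and optional pruning retention.
#' @param script a [change_script()] of planted changes.
#' @param sar_years years with SAR collections (`I = 4`); other years run
#'   optical-only (`I = 2`). Default: all years.
#' @param seed master seed; per-stage seeds derive from it.
#' @param out_dir optional directory for written artifacts with
#'   provenance sidecars.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(years, ref_year = max(years),
                            grid = grid_spec(96, 96), n_classes = 6L,
                            separation = 5, noise_sd = 0.02,
                            scenes_per_season = 3L, cloud_fraction = 0.2,
                            n_training_per_class = 200L,
                            n_validation_per_class = 100L,
                            rule = migration_rule(),
                            settings = rf_settings(),
                            c = 0.7, retention = NULL,
                            script = change_script(),
                            sar_years = years, seed = 1L, out_dir = NULL) {
  stopifnot(all(diff(years) > 0), ref_year %in% years)
  structure(list(years = years, ref_year = ref_year, grid = grid,
                 n_classes = as.integer(n_classes), separation = separation,
                 noise_sd = noise_sd,
                 scenes_per_season = as.integer(scenes_per_season),
                 cloud_fraction = cloud_fraction,
                 n_training_per_class = as.integer(n_training_per_class),
                 n_validation_per_class = as.integer(n_validation_per_class),
                 rule = rule, settings = settings, c = c,
                 retention = retention, script = script,
                 sar_years = sar_years, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage_seed <- function(config, year, stage) {
  # small deterministic per-(year, stage) seed, kept well under 2^31
  (config$seed * 1009L + (year %% 1000L) * 131L +
     sum(utf8ToInt(stage))) %% 100000L
}

write_provenance <- function(path, stage, inputs, params, seed) {
  jsonlite::write_json(
    list(stage = stage, inputs = inputs, params = params, seed = seed,
         package = "annualcover",
         version = as.character(utils::packageVersion("annualcover"))),
    paste0(path, ".prov.json"), auto_unbox = TRUE, digits = NA)
}

#' Simulate the full multi-year data set of a configuration
#'
#' @param config a [pipeline_config()].
#' @return A list with `model` (class spectra), `truth` (per-year label
#'   rasters), and `scenes` (per-year output of [simulate_year()]).
#' @export
simulate_dataset <- function(config) {
  model <- make_class_spectra(config$n_classes,
                              separation = config$separation,
                              noise_sd = config$noise_sd,
                              seed = stage_seed(config, 0L, "spectra"))
  base <- simulate_label_map(config$grid, model$class_ids,
                             seed = stage_seed(config, 0L, "labels"))
  truth <- apply_change_script(base, config$script, config$years,
                               seed = stage_seed(config, 0L, "change"))
  scenes <- lapply(config$years, function(y) {
    simulate_year(model, truth[[as.character(y)]], y,
                  scenes_per_season = config$scenes_per_season,
                  cloud_fraction = config$cloud_fraction,
                  seed = stage_seed(config, y, "scenes"))
  })
  names(scenes) <- as.character(config$years)
  list(model = model, truth = truth, scenes = scenes)
}

#' Classify one year of a simulated series
#'
#' Executes the per-year stages in order — composite, indices, covariate
#' collections, training (migrated unless `year` is the reference year),
#' fused classification, and stratified assessment against truth — and
#' optionally writes the label raster and metrics with provenance
#' sidecars.
#'
#' @param config a [pipeline_config()].
#' @param year the year to classify.
#' @param data output of [simulate_dataset()].
#' @param training reference-year training samples; `NULL` draws them from
#'   the reference year's truth.
#' @param ref_signature annual six-band signature composite of the
#'   reference year ([annual_signature_composite()]); `NULL` computes it.
#' @return A list with `labels` (the classified map), `metrics`,
#'   `migration` (report or `NULL` for the reference year), `collections`
#'   used, and `oa`.
#' @export
run_year <- function(config, year, data, training = NULL,
                     ref_signature = NULL) {
  ykey <- as.character(year)
  if (!ykey %in% names(data$scenes)) stop("year not simulated: ", year,
                                          call. = FALSE)
  use_sar <- year %in% config$sar_years
  yd <- data$scenes[[ykey]]
  collections <- make_covariate_collections(
    yd$optical, if (use_sar) yd$sar else NULL)
  truth_ref <- data$truth[[as.character(config$ref_year)]]
  if (is.null(training))
    training <- sample_training(truth_ref, config$n_training_per_class,
                                year = config$ref_year,
                                seed = stage_seed(config, config$ref_year,
                                                  "training"))
  migration <- NULL
  if (year != config$ref_year) {
    if (is.null(ref_signature)) {
      rd <- data$scenes[[as.character(config$ref_year)]]
      ref_signature <- annual_signature_composite(
        medoid_composite(rd$optical$dry), medoid_composite(rd$optical$wet))
    }
    target_signature <- annual_signature_composite(
      medoid_composite(yd$optical$dry), medoid_composite(yd$optical$wet))
    res <- migrate_training(training, ref_signature, target_signature,
                            rule = config$rule, target_year = year)
    training <- res$training
    migration <- res$report
    if (!nrow(training)) stop("migration retained no samples", call. = FALSE)
  }
  fit <- fusion_forest(collections, training, c = config$c,
                       N = config$n_classes, retention = config$retention,
                       settings = config$settings)
  labels <- predict(fit, collections)
  truth_y <- data$truth[[ykey]]
  val <- sample_training(truth_y, config$n_validation_per_class,
                         year = year,
                         seed = stage_seed(config, year, "validation"))
  val <- setdiff_samples(val, training)
  idx <- cbind(val$row + 1L, val$col + 1L)
  pred <- labels$values[idx]
  keep <- !is.na(pred)
  cm <- confusion(val$class_id[keep], pred[keep],
                  classes = data$model$class_ids, level = labels$level)
  metrics <- accuracy_metrics(cm)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    lp <- file.path(config$out_dir, sprintf("labels_%d.tif", year))
    write_label_raster(labels, lp)
    write_provenance(lp, "classify",
                     inputs = list(year = year,
                                   collections = names(collections)),
                     params = list(c = config$c,
                                   num_trees = config$settings$num_trees,
                                   max_features = config$settings$max_features),
                     seed = config$settings$seed)
    mp <- file.path(config$out_dir, sprintf("confusion_%d.csv", year))
    write_confusion_csv(cm, mp)
    write_provenance(mp, "assess",
                     inputs = list(year = year,
                                   n_per_class = config$n_validation_per_class),
                     params = list(), seed = stage_seed(config, year,
                                                        "validation"))
  }
  list(labels = labels, metrics = metrics, confusion = cm,
       migration = migration, collections = names(collections),
       oa = metrics$OA)
}

#' Run the full multi-year series
#'
#' Simulates the configured data set (unless supplied), classifies every
#' year with training migrated from the reference year, and derives the
#' change products: per-pixel change frequency, the class-area series,
#' annualized net-change rates with their 0-100 dynamism rescaling, and
#' consecutive-year transition matrices.
#'
#' @param config a [pipeline_config()].
#' @param data optional pre-simulated [simulate_dataset()] output.
#' @return A list with `years`, `maps`, `metrics`, `migrations`,
#'   `change` (list of `frequency`, `areas`, `rates`, `rates_rescaled`,
#'   `transitions`), and `data`.
#' @export
run_series <- function(config, data = NULL) {
  stopifnot(length(config$years) >= 2)
  data <- data %||% simulate_dataset(config)
  truth_ref <- data$truth[[as.character(config$ref_year)]]
  training <- sample_training(truth_ref, config$n_training_per_class,
                              year = config$ref_year,
                              seed = stage_seed(config, config$ref_year,
                                                "training"))
  rd <- data$scenes[[as.character(config$ref_year)]]
  ref_signature <- annual_signature_composite(
    medoid_composite(rd$optical$dry), medoid_composite(rd$optical$wet))
  runs <- lapply(config$years, function(y)
    run_year(config, y, data, training = training,
             ref_signature = ref_signature))
  names(runs) <- as.character(config$years)
  maps <- lapply(runs, `[[`, "labels")
  areas <- area_series(maps, config$years)
  classes <- sort(unique(areas$class))
  y1 <- config$years[1]; y2 <- config$years[length(config$years)]
  rates <- vapply(classes, function(cl)
    net_change_percent(areas, cl, y1, y2), numeric(1))
  names(rates) <- classes
  transitions <- lapply(seq_len(length(config$years) - 1L), function(i)
    transition_matrix(maps[[i]], maps[[i + 1L]]))
  names(transitions) <- paste(config$years[-length(config$years)],
                              config$years[-1], sep = "_")
  list(years = config$years, maps = maps,
       metrics = lapply(runs, `[[`, "metrics"),
       migrations = lapply(runs, `[[`, "migration"),
       change = list(frequency = change_frequency(maps),
                     areas = areas, rates = rates,
                     rates_rescaled = rescale_rates(rates),
                     transitions = transitions),
       data = data)
}
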