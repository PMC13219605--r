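#' End-to-end lethal-heatwave pipeline
#'
#' Orchestrates the whole analysis on a synthetic corpus: generate (or take)
#' a corpus, split chronologically by region, resample the training
#' partition, train and Platt-calibrate the forest, evaluate against the
#' wet-bulb-threshold baselines and a temperature+humidity-only model,
#' compute permutation importance, and assign the Shock/Threshold taxonomy
#' to test-set predictions.
#'
#' @param config list with elements (all optional, defaults shown by
#'   [pipeline_config()]): `weather` ([weather_params()]), `mechanism`
#'   ([lethality_mechanism()]), `extraction` (list: percentile, min_duration,
#'   n_windows, n_adaptive, m), `split` (list: test_frac, val_frac,
#'   region_key, seed), `recipe` ([train_recipe()]), `wbt_thresholds`
#'   (baseline grid, degrees C), `importance_repeats`, `run_selection`
#'   (logical), `shock_cutoff`.  Unknown keys are rejected.
#' @param corpus optionally, a pre-generated `heat_corpus` (skips
#'   simulation).
#' @param quiet suppress stage logging.
#' @return list of class `heat_pipeline`: `corpus`, `split`, `model`,
#'   `metrics` (test partition), `baselines` (per WBT threshold),
#'   `temp_humid_metrics`, `importance`, `selection` (or NULL), `taxonomy`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), corpus = NULL,
                         quiet = FALSE) {
  config <- do.call(pipeline_config, config)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (is.null(corpus)) {
    say("simulate: %d cities x %d years", config$weather$n_cities,
        config$weather$years)
    corpus <- stage("simulate", do.call(generate_corpus, c(
      list(weather = config$weather, mech = config$mechanism),
      config$extraction)))
  }
  ev <- corpus$events
  feats <- corpus$features[, feature_names()]
  say("corpus: %d events, %.3f%% lethal", nrow(ev), 100 * mean(ev$lethal))

  sp <- stage("split", temporal_split(
    ev, test_frac = config$split$test_frac, val_frac = config$split$val_frac,
    region_key = config$split$region_key, seed = config$split$seed))
  part <- sp$partition
  idx <- split(seq_len(nrow(ev)), part)
  say("split: %d train / %d validation / %d test",
      length(idx$train), length(idx$validation), length(idx$test))

  model <- stage("train", train_model(
    config$recipe,
    feats[idx$train, ], ev$lethal[idx$train],
    feats[idx$validation, ], ev$lethal[idx$validation]))

  test_x <- feats[idx$test, ]
  test_y <- ev$lethal[idx$test]
  pred <- classify(model, test_x)
  metrics <- compute_metrics(test_y, pred)
  say("test: F1 %.3f (precision %.3f, recall %.3f)",
      metrics$f1, metrics$precision, metrics$recall)

  baselines <- stage("baselines", lapply(config$wbt_thresholds, function(thr)
    wbt_threshold_classifier(ev[idx$test, ], thr)$metrics))
  names(baselines) <- paste0("wbt_", config$wbt_thresholds)

  th_model <- stage("temp_humid_model", train_model(
    config$recipe,
    feats[idx$train, ], ev$lethal[idx$train],
    feats[idx$validation, ], ev$lethal[idx$validation],
    features = c("max_temp", "mean_humid")))
  temp_humid_metrics <- compute_metrics(
    test_y, classify(th_model, test_x[, c("max_temp", "mean_humid")]))

  importance <- stage("importance", permutation_importance(
    model, test_x, test_y, n_repeats = config$importance_repeats,
    seed = config$split$seed))

  selection <- NULL
  if (isTRUE(config$run_selection)) {
    say("forward selection over %d candidates", length(feature_names()))
    selection <- stage("selection", forward_selection(
      config$recipe,
      feats[idx$train, ], ev$lethal[idx$train],
      feats[idx$validation, ], ev$lethal[idx$validation],
      test_x, test_y))
  }

  taxonomy <- stage("taxonomy", assign_taxonomy(
    ev[idx$test, ], lethal = pred, shock_cutoff = config$shock_cutoff))

  structure(list(corpus = corpus, split = sp, model = model,
                 metrics = metrics, baselines = baselines,
                 temp_humid_metrics = temp_humid_metrics,
                 importance = importance, selection = selection,
                 taxonomy = taxonomy, config = config),
            class = "heat_pipeline")
}

#' Default pipeline configuration
#'
#' @param weather,mechanism,extraction,split,recipe,wbt_thresholds,importance_repeats,run_selection,shock_cutoff
#'   see [run_pipeline()].
#' @return validated configuration list.
#' @export
pipeline_config <- function(weather = weather_params(),
                            mechanism = lethality_mechanism(),
                            extraction = list(),
                            split = list(),
                            recipe = train_recipe(),
                            wbt_thresholds = c(20, 25, 30, 35),
                            importance_repeats = 10,
                            run_selection = FALSE,
                            shock_cutoff = 25) {
  split_def <- list(test_frac = 0.10, val_frac = 0.10,
                    region_key = "city_id", seed = 1L)
  bad <- setdiff(names(split), names(split_def))
  if (length(bad))
    stop_config("pipeline_config: unknown split keys: %s", paste(bad, collapse = ", "))
  split_def[names(split)] <- split
  extraction_def <- list(percentile = 0.90, min_duration = 2,
                         n_windows = c(30, 90, 180), n_adaptive = 30, m = 10)
  bad <- setdiff(names(extraction), names(extraction_def))
  if (length(bad))
    stop_config("pipeline_config: unknown extraction keys: %s",
                paste(bad, collapse = ", "))
  extraction_def[names(extraction)] <- extraction
  list(weather = weather, mechanism = mechanism, extraction = extraction_def,
       split = split_def, recipe = recipe, wbt_thresholds = wbt_thresholds,
       importance_repeats = importance_repeats,
       run_selection = run_selection, shock_cutoff = shock_cutoff)
}

#' @export
print.heat_pipeline <- function(x, ...) {
  cat("<heat_pipeline>\n  test metrics: ")
  print(x$metrics)
  best_wbt <- max(vapply(x$baselines, function(m) m$f1, numeric(1)))
  cat(sprintf("  best WBT baseline F1: %.3f; temp+humid-only F1: %.3f\n",
              best_wbt, x$temp_humid_metrics$f1))
  tab <- table(x$taxonomy$taxonomy)
  cat("  taxonomy (test predictions):",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
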