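#' Training recipe: resampling + forest + Platt calibration
#'
#' Bundles the settings needed to train the lethality classifier
#' reproducibly, so sensitivity analyses (feature dropout, forward selection)
#' can retrain under identical conditions on feature subsets.
#'
#' @param resample a [resample_spec()] applied to the training partition only
#'   (default: SMOTE to a 1:1 ratio, which outperformed downsampling on
#'   validation F1 in the study design this mirrors).
#' @param n_trees,mtry,min_node_size forest hyperparameters
#'   (see [fit_forest()]).
#' @param decision_threshold calibrated-probability decision threshold
#'   (default 0.6).
#' @param seed integer seed governing resampling and tree growing.
#' @return object of class `train_recipe`.
#' @export
train_recipe <- function(resample = resample_spec("smote"),
                         n_trees = 500, mtry = NULL, min_node_size = 1,
                         decision_threshold = 0.6, seed = 1L) {
  structure(list(resample = resample, n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size,
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "train_recipe")
}

#' Train a calibrated classifier from a recipe
#'
#' Resamples the training partition per the recipe, fits the vote forest on
#' the (possibly restricted) feature set, then Platt-calibrates on the
#' disjoint calibration partition.
#'
#' @param recipe a [train_recipe()].
#' @param x_train,y_train training partition.
#' @param x_cal,y_cal calibration (validation) partition.
#' @param features optional character subset of columns to train on
#'   (default: all columns of `x_train`).  Resampling (SMOTE neighbour
#'   search) is re-run inside this subspace.
#' @param seed overrides the recipe seed if given.
#' @return a `calibrated_classifier`.
#' @export
train_model <- function(recipe, x_train, y_train, x_cal, y_cal,
                        features = NULL, seed = recipe$seed) {
  stopifnot(inherits(recipe, "train_recipe"))
  features <- features %||% names(x_train)
  xt <- x_train[, features, drop = FALSE]
  xc <- x_cal[, features, drop = FALSE]
  rs <- recipe$resample
  rs$seed <- as.integer(seed)
  r <- apply_resample(xt, y_train, rs)
  forest <- fit_forest(r$features, r$labels, n_trees = recipe$n_trees,
                       mtry = recipe$mtry,
                       min_node_size = recipe$min_node_size, seed = seed)
  fit_platt(forest, xc, y_cal,
            decision_threshold = recipe$decision_threshold)
}

#' Small seeded grid search over forest hyperparameters
#'
#' Trains one model per grid point and scores F1 on the validation
#' partition; returns the grid with scores and the best settings.  Stands in
#' for the study's model-optimisation step; the default grid is deliberately
#' small.
#'
#' @param recipe base [train_recipe()].
#' @param x_train,y_train,x_val,y_val partitions.
#' @param grid data frame of hyperparameter combinations with any of the
#'   columns `n_trees`, `mtry`, `min_node_size`.
#' @return list with `grid` (scores appended) and `best` (a `train_recipe`).
#' @export
tune_forest <- function(recipe, x_train, y_train, x_val, y_val,
                        grid = expand.grid(mtry = c(2, 4, 6),
                                           min_node_size = c(1, 5))) {
  f1 <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- recipe
    for (nm in names(grid)) r[[nm]] <- grid[[nm]][i]
    clf <- train_model(r, x_train, y_train, x_val, y_val)
    f1[i] <- compute_metrics(y_val, classify(clf, x_val))$f1
  }
  grid$f1 <- f1
  best <- recipe
  for (nm in setdiff(names(grid), "f1")) best[[nm]] <- grid[[nm]][which.max(f1)]
  list(grid = grid, best = best)
}
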