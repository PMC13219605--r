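#' Permutation feature importance
#'
#' For each feature, independently shuffles that column of the held-out data
#' `n_repeats` times and records the decrease in F1 relative to the
#' unshuffled baseline.  Importance concentrates on features the model
#' actually uses, but is shared between highly correlated features.
#'
#' @param clf a `calibrated_classifier`.
#' @param features held-out feature data frame.
#' @param labels held-out 0/1 labels.
#' @param n_repeats shuffles per feature (default 10, minimum 1).
#' @param seed integer seed for the shuffles.
#' @return data frame of class `importance_report`: `feature`,
#'   `mean_decrease` (baseline F1 minus permuted F1, averaged), `sd_decrease`;
#'   attribute `baseline_f1`.
#' @export
permutation_importance <- function(clf, features, labels, n_repeats = 10,
                                   seed = 1L) {
  if (n_repeats < 1) stop_config("permutation_importance: n_repeats must be >= 1")
  fns <- clf$forest$feature_names
  baseline <- compute_metrics(labels, classify(clf, features))$f1
  set.seed(as.integer(seed))
  dec <- matrix(NA_real_, n_repeats, length(fns), dimnames = list(NULL, fns))
  for (f in fns) {
    for (r in seq_len(n_repeats)) {
      xp <- features
      xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
      dec[r, f] <- baseline - compute_metrics(labels, classify(clf, xp))$f1
    }
  }
  out <- data.frame(feature = fns,
                    mean_decrease = colMeans(dec),
                    sd_decrease = apply(dec, 2, stats::sd),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "baseline_f1") <- baseline
  class(out) <- c("importance_report", class(out))
  out
}

#' Dropout (drop-column) feature importance
#'
#' For each feature, retrains the full recipe without that feature and
#' records the decrease in held-out F1 relative to the full model.  Unlike
#' permutation importance, information shared with correlated features is
#' recovered by the retrained model, so dropout decreases are typically
#' smaller.
#'
#' @param recipe a [train_recipe()].
#' @param x_train,y_train,x_cal,y_cal training and calibration partitions.
#' @param x_eval,y_eval held-out evaluation partition.
#' @param features features to drop in turn (default: all columns).
#' @return data frame: `feature`, `dropout_decrease`; attribute
#'   `baseline_f1` (full-model F1 on the evaluation partition).
#' @export
dropout_importance <- function(recipe, x_train, y_train, x_cal, y_cal,
                               x_eval, y_eval, features = names(x_train)) {
  miss <- setdiff(features, names(x_train))
  if (length(miss))
    stop_config("dropout_importance: unknown feature(s): %s",
                paste(miss, collapse = ", "))
  full <- train_model(recipe, x_train, y_train, x_cal, y_cal)
  baseline <- compute_metrics(y_eval, classify(full, x_eval))$f1
  dec <- vapply(features, function(f) {
    keep <- setdiff(names(x_train), f)
    clf <- train_model(recipe, x_train, y_train, x_cal, y_cal, features = keep)
    baseline - compute_metrics(y_eval, classify(clf, x_eval))$f1
  }, numeric(1))
  out <- data.frame(feature = features, dropout_decrease = unname(dec),
                    stringsAsFactors = FALSE)
  attr(out, "baseline_f1") <- baseline
  out
}

#' Greedy forward feature selection
#'
#' Starting from an empty set, adds at each step the candidate feature whose
#' addition maximises F1 on the selection partition (ties broken by
#' candidate order), retraining the full recipe each time.  The selection
#' signal never touches the test partition; per-step metrics are additionally
#' reported on the held-out test partition when given.
#'
#' @param recipe a [train_recipe()].
#' @param x_train,y_train,x_cal,y_cal training and calibration/selection
#'   partitions (selection F1 is scored on `x_cal`, `y_cal`).
#' @param x_test,y_test optional test partition for per-step reporting.
#' @param candidates candidate feature names (default: all columns).
#' @param max_steps stop after this many steps (default: all candidates).
#' @return data frame ladder: `step`, `feature`, `val_f1`, and test metrics
#'   per step when a test partition is supplied.
#' @export
forward_selection <- function(recipe, x_train, y_train, x_cal, y_cal,
                              x_test = NULL, y_test = NULL,
                              candidates = names(x_train),
                              max_steps = length(candidates)) {
  if (!length(candidates)) stop_config("forward_selection: no candidates")
  chosen <- character()
  rows <- list()
  remaining <- candidates
  for (step in seq_len(min(max_steps, length(candidates)))) {
    f1s <- vapply(remaining, function(f) {
      clf <- train_model(recipe, x_train, y_train, x_cal, y_cal,
                         features = c(chosen, f))
      compute_metrics(y_cal, classify(clf, x_cal[, c(chosen, f), drop = FALSE]))$f1
    }, numeric(1))
    best <- remaining[which.max(f1s)]  # which.max takes the first maximum:
    chosen <- c(chosen, best)          # ties break by candidate order
    remaining <- setdiff(remaining, best)
    row <- data.frame(step = step, feature = best, val_f1 = max(f1s),
                      stringsAsFactors = FALSE)
    if (!is.null(x_test)) {
      clf <- train_model(recipe, x_train, y_train, x_cal, y_cal,
                         features = chosen)
      m <- compute_metrics(y_test, classify(clf, x_test[, chosen, drop = FALSE]))
      row$test_accuracy <- m$accuracy
      row$test_precision <- m$precision
      row$test_recall <- m$recall
      row$test_f1 <- m$f1
    }
    rows[[step]] <- row
  }
  do.call(rbind, rows)
}

#' Pearson correlation matrix of the predictors
#'
#' Zero-variance columns are flagged and their correlations reported as 0.
#'
#' @param features feature data frame (>= 2 rows).
#' @return correlation matrix with attribute `zero_variance` naming any
#'   constant columns.
#' @export
feature_correlation <- function(features) {
  if (nrow(features) < 2)
    stop_config("feature_correlation: need at least 2 events")
  x <- as.matrix(features)
  sdv <- apply(x, 2, stats::sd)
  zv <- names(which(sdv == 0 | !is.finite(sdv)))
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  if (length(zv)) attr(cm, "zero_variance") <- zv
  cm
}
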