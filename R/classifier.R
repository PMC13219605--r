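#' Fit the random-forest vote ensemble
#'
#' Bootstrap-bagged decision trees with random feature subsets at each split
#' (via ranger).  The raw classifier score of an event is the fraction of
#' trees voting lethal, which the Platt layer later maps to a calibrated
#' probability.
#'
#' @param features training feature data frame.
#' @param labels 0/1 training labels; both classes must be present.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default floor(sqrt(p))).
#' @param min_node_size minimal terminal node size (default 1, i.e. trees
#'   grown to purity).
#' @param seed integer seed; fits are deterministic given data and seed.
#' @return object of class `heat_forest`.
#' @export
fit_forest <- function(features, labels, n_trees = 500, mtry = NULL,
                       min_node_size = 1, seed = 1L) {
  if (length(unique(labels)) < 2)
    stop_config("fit_forest: training labels contain a single class")
  if (nrow(features) != length(labels))
    stop_config("fit_forest: features and labels not aligned")
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  fit <- ranger::ranger(
    x = features, y = y,
    num.trees = n_trees,
    mtry = mtry %||% max(1L, floor(sqrt(ncol(features)))),
    min.node.size = min_node_size,
    num.threads = 1L, seed = as.integer(seed),
    verbose = FALSE)
  structure(list(fit = fit, feature_names = names(features),
                 n_trees = n_trees, seed = as.integer(seed)),
            class = "heat_forest")
}

#' Raw forest score: fraction of trees voting lethal
#'
#' @param forest a `heat_forest`.
#' @param features data frame with the training feature columns.
#' @return numeric vector in \[0, 1\].
#' @export
raw_score <- function(forest, features) {
  stopifnot(inherits(forest, "heat_forest"))
  miss <- setdiff(forest$feature_names, names(features))
  if (length(miss))
    stop_config("raw_score: missing feature(s): %s", paste(miss, collapse = ", "))
  x <- features[, forest$feature_names, drop = FALSE]
  pa <- stats::predict(forest$fit, data = x, predict.all = TRUE,
                       num.threads = 1L)$predictions
  # per-tree predictions index the factor levels of the training response
  lv <- forest$fit$forest$levels
  rowMeans(matrix(lv[pa] == "1", nrow(pa)))
}

#' Platt-scale a forest on held-out calibration data
#'
#' Fits a logistic regression of the calibration labels on the raw vote
#' fraction by maximum likelihood, mapping raw scores s to calibrated
#' probabilities sigma(a s + b).  The calibration set must be disjoint from
#' the forest's training data (the validation partition in the pipeline),
#' otherwise the map inherits the training optimism.
#'
#' @param forest a fitted `heat_forest`.
#' @param features,labels calibration data; both classes must be present.
#' @param decision_threshold probability above which an event is classified
#'   lethal (default 0.6).
#' @return object of class `calibrated_classifier` with elements `forest`,
#'   `platt_a`, `platt_b`, `decision_threshold`.
#' @export
fit_platt <- function(forest, features, labels, decision_threshold = 0.6) {
  if (length(unique(labels)) < 2)
    stop_config("fit_platt: calibration labels contain a single class")
  s <- raw_score(forest, features)
  co <- platt_coefficients(s, labels)
  structure(list(forest = forest, platt_a = co[["a"]], platt_b = co[["b"]],
                 decision_threshold = decision_threshold),
            class = "calibrated_classifier")
}

# logistic MLE of labels on scores; exposed internally for recovery tests
platt_coefficients <- function(scores, labels) {
  fit <- suppressWarnings(
    stats::glm(labels ~ scores, family = stats::binomial()))
  c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
}

#' Calibrated lethality probability
#'
#' @param clf a `calibrated_classifier`.
#' @param features feature data frame.
#' @return probabilities in (0, 1).
#' @export
predict_probability <- function(clf, features) {
  stopifnot(inherits(clf, "calibrated_classifier"))
  s <- raw_score(clf$forest, features)
  stats::plogis(clf$platt_a * s + clf$platt_b)
}

#' Threshold classification
#'
#' An event is classified lethal when its calibrated probability reaches the
#' decision threshold; ties at the threshold classify lethal, since
#' under-prediction of lethal heat is the more damaging error.
#'
#' @param clf a `calibrated_classifier`.
#' @param features feature data frame.
#' @param threshold decision threshold in (0, 1); defaults to the one stored
#'   in the classifier (0.6).
#' @return integer 0/1 predictions.
#' @export
classify <- function(clf, features, threshold = clf$decision_threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop_config("classify: threshold must be in (0, 1)")
  as.integer(predict_probability(clf, features) >= threshold)
}
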