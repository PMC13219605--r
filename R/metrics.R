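#' Confusion-matrix metrics for imbalanced classification
#'
#' Computes accuracy, precision (TP / (TP + FP)), recall (TP / (TP + FN)) and
#' F1 (harmonic mean of precision and recall).  With lethal events under 1
#' percent of the catalogue, accuracy is nearly useless (always predicting
#' nonlethal scores about 0.992), so precision/recall/F1 carry the weight.
#' A ratio with zero denominator is reported as 0 and flagged in the
#' `undefined` field, keeping metric ladders totally ordered.
#'
#' @param truth 0/1 vector of true labels.
#' @param predicted 0/1 vector of predictions, same length.
#' @return list of class `metrics_report`: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `precision`, `recall`, `f1`, `undefined` (character vector
#'   of metrics whose denominator was zero).
#' @export
compute_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_config("compute_metrics: length mismatch (%d vs %d)",
                length(truth), length(predicted))
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  fn <- sum(truth == 1 & predicted == 0)
  undefined <- character()
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    if (!"f1" %in% undefined) undefined <- c(undefined, "f1")
    0
  } else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = safe(tp + tn, tp + fp + tn + fn, "accuracy"),
                 precision = precision, recall = recall, f1 = f1,
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  (TP %d FP %d TN %d FN %d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$tp, x$fp, x$tn, x$fn))
  if (length(x$undefined))
    cat("  zero-denominator metrics reported as 0:",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Wet-bulb-temperature threshold baseline classifier
#'
#' The conventional alternative to a learned model: predict lethal whenever
#' the event's Stull wet-bulb temperature (from its maximum temperature and
#' mean humidity) reaches a fixed threshold.
#'
#' @param events event rows with `tmax` and `rh_mean` (and `lethal` if
#'   metrics are wanted).
#' @param wbt_threshold threshold in degrees C (e.g. 20, 25, 30, 35).
#' @param truth optional 0/1 labels; defaults to `events$lethal`.
#' @return list with `predicted` (0/1) and `metrics` (a `metrics_report`,
#'   or NULL when no labels are available).
#' @export
wbt_threshold_classifier <- function(events, wbt_threshold, truth = events$lethal) {
  wbt <- as.numeric(stull_wbt(events$tmax, events$rh_mean))
  predicted <- as.integer(wbt >= wbt_threshold)
  list(predicted = predicted,
       metrics = if (!is.null(truth)) compute_metrics(truth, predicted))
}
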