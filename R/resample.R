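#' Random downsampling of the majority class
#'
#' Keeps every minority (lethal) example and a seeded uniform sample of
#' `keep_fraction` of the majority.  Applied to training data only.
#'
#' @param features feature data frame.
#' @param labels 0/1 vector, minority coded 1.
#' @param keep_fraction fraction of majority rows to retain, in (0, 1].
#' @param seed integer seed.
#' @return list with `features`, `labels`.
#' @export
downsample_majority <- function(features, labels, keep_fraction, seed = 1L) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_config("downsample_majority: keep_fraction must be in (0, 1]")
  if (nrow(features) != length(labels))
    stop_config("downsample_majority: features and labels not aligned")
  maj <- which(labels == 0)
  minr <- which(labels == 1)
  set.seed(as.integer(seed))
  keep_maj <- sort(sample(maj, round(keep_fraction * length(maj))))
  keep <- sort(c(minr, keep_maj))
  list(features = features[keep, , drop = FALSE], labels = labels[keep])
}

#' SMOTE: synthetic minority oversampling
#'
#' Synthesises new minority (lethal) examples by linear interpolation between
#' a minority point and one of its k nearest minority neighbours:
#' `x_new = x_i + u (x_nn - x_i)` with `u ~ Uniform(0, 1)`.  Neighbours are
#' found by Euclidean distance in per-feature standardised coordinates
#' (features mix degrees C, percent and kg/m2), but interpolation happens in
#' the original coordinates, so every synthetic point lies inside the convex
#' hull of the minority class.  Originals are kept untouched; synthesis
#' continues until the minority:majority ratio reaches `target_ratio`.
#'
#' @param features feature data frame (numeric columns only).
#' @param labels 0/1 vector, minority coded 1; minority count must exceed
#'   `k`.
#' @param k number of nearest minority neighbours (default 5).
#' @param target_ratio desired minority:majority ratio after resampling
#'   (default 1).
#' @param seed integer seed.
#' @return list with `features`, `labels` and `synthetic` (logical flag per
#'   row).
#' @export
smote <- function(features, labels, k = 5, target_ratio = 1, seed = 1L) {
  if (nrow(features) != length(labels))
    stop_config("smote: features and labels not aligned")
  if (k < 1) stop_config("smote: k must be >= 1")
  minr <- which(labels == 1)
  n_min <- length(minr)
  n_maj <- sum(labels == 0)
  if (n_min <= k)
    stop_config("smote: minority count (%d) must exceed k (%d); use a smaller k",
                n_min, k)
  n_new <- max(0L, round(target_ratio * n_maj) - n_min)
  if (n_new == 0L)
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, length(labels))))
  xm <- as.matrix(features[minr, , drop = FALSE])
  mu <- colMeans(xm)
  sdv <- apply(xm, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(xm, 2, mu), 2, sdv, "/")
  dm <- as.matrix(stats::dist(z))
  diag(dm) <- Inf
  nn <- apply(dm, 1, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1) matrix(nn, ncol = 1) else t(nn)

  set.seed(as.integer(seed))
  base_i <- sample.int(n_min, n_new, replace = TRUE)
  nn_j <- nn[cbind(base_i, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  synth <- xm[base_i, , drop = FALSE] +
    u * (xm[nn_j, , drop = FALSE] - xm[base_i, , drop = FALSE])
  synth <- as.data.frame(synth)
  names(synth) <- names(features)
  list(features = rbind(features, synth),
       labels = c(labels, rep(1L, n_new)),
       synthetic = c(rep(FALSE, length(labels)), rep(TRUE, n_new)))
}

#' Specification of a training-set resampling strategy
#'
#' @param strategy one of `"none"`, `"downsample"`, `"smote"`.
#' @param keep_fraction majority fraction kept when downsampling.
#' @param k SMOTE neighbour count (default 5).
#' @param target_ratio minority:majority ratio after resampling (default 1).
#' @param seed integer seed.
#' @return object of class `resample_spec`.
#' @export
resample_spec <- function(strategy = c("smote", "downsample", "none"),
                          keep_fraction = 0.5, k = 5, target_ratio = 1,
                          seed = 1L) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy, keep_fraction = keep_fraction,
                 k = k, target_ratio = target_ratio, seed = as.integer(seed)),
            class = "resample_spec")
}

#' Apply a resampling specification to a training set
#'
#' @param features,labels training data.
#' @param spec a [resample_spec()].
#' @return list with `features`, `labels`.
#' @export
apply_resample <- function(features, labels, spec) {
  stopifnot(inherits(spec, "resample_spec"))
  switch(spec$strategy,
         none = list(features = features, labels = labels),
         downsample = downsample_majority(features, labels,
                                          spec$keep_fraction, spec$seed),
         smote = smote(features, labels, k = spec$k,
                       target_ratio = spec$target_ratio, seed = spec$seed))
}
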