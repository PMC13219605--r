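# a dataset where `driver` determines the label and `noise` is pure noise
driver_data <- function(n = 600, seed = 61, dup_driver = FALSE) {
  set.seed(seed)
  x <- data.frame(driver = rnorm(n), other = rnorm(n), noise = rnorm(n))
  if (dup_driver) x$driver2 <- x$driver
  y <- as.integer(x$driver + 0.3 * x$other + rnorm(n, 0, 0.4) > 1)
  list(x = x, y = y)
}

test_that("permutation importance separates driver from pure noise", {
  d <- driver_data()
  tr <- 1:400; ho <- 401:600
  fo <- fit_forest(d$x[tr, ], d$y[tr], n_trees = 150, seed = 5)
  clf <- fit_platt(fo, d$x[ho, ], d$y[ho], decision_threshold = 0.5)
  imp <- permutation_importance(clf, d$x[ho, ], d$y[ho], n_repeats = 10, seed = 6)
  expect_setequal(imp$feature, names(d$x))
  drv <- imp$mean_decrease[imp$feature == "driver"]
  nse <- imp$mean_decrease[imp$feature == "noise"]
  expect_gt(drv, nse)
  expect_gt(drv, 0.1)
  # a pure-noise column has importance within 2 sd of zero
  expect_lt(abs(nse), 2 * max(imp$sd_decrease[imp$feature == "noise"], 1e-3))
  expect_error(permutation_importance(clf, d$x[ho, ], d$y[ho], n_repeats = 0),
               "n_repeats")
})

test_that("importance is shared between duplicated copies of the driver", {
  d1 <- driver_data(seed = 62)
  d2 <- driver_data(seed = 62, dup_driver = TRUE)
  tr <- 1:400; ho <- 401:600
  imp_of <- function(d) {
    fo <- fit_forest(d$x[tr, ], d$y[tr], n_trees = 200, seed = 7)
    clf <- fit_platt(fo, d$x[ho, ], d$y[ho], decision_threshold = 0.5)
    permutation_importance(clf, d$x[ho, ], d$y[ho], n_repeats = 10, seed = 8)
  }
  i1 <- imp_of(d1)
  i2 <- imp_of(d2)
  single <- i1$mean_decrease[i1$feature == "driver"]
  dup <- i2$mean_decrease[i2$feature %in% c("driver", "driver2")]
  expect_true(all(dup < single))
})

test_that("dropout importance vanishes for constants and duplicated features", {
  d <- driver_data(seed = 63)
  d$x$flat <- 1  # constant column
  tr <- 1:400; ho <- 401:600
  rec <- train_recipe(resample = resample_spec("none"), n_trees = 150,
                      decision_threshold = 0.5, seed = 9)
  di <- dropout_importance(rec, d$x[tr, ], d$y[tr], d$x[ho, ], d$y[ho],
                           d$x[ho, ], d$y[ho])
  expect_lt(abs(di$dropout_decrease[di$feature == "flat"]), 0.02)
  expect_gt(di$dropout_decrease[di$feature == "driver"], 0.05)

  # dropping one of two perfect copies loses nothing
  d2 <- driver_data(seed = 63, dup_driver = TRUE)
  di2 <- dropout_importance(rec, d2$x[tr, ], d2$y[tr], d2$x[ho, ], d2$y[ho],
                            d2$x[ho, ], d2$y[ho], features = "driver")
  expect_lt(abs(di2$dropout_decrease), 0.1)
  expect_error(dropout_importance(rec, d$x[tr, ], d$y[tr], d$x[ho, ], d$y[ho],
                                  d$x[ho, ], d$y[ho], features = "nope"),
               "unknown feature")
})

test_that("forward selection picks a perfect separator first and builds a ladder", {
  set.seed(64)
  n <- 400
  x <- data.frame(weak = rnorm(n), perfect = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                  noise = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  ord <- sample(n)
  x <- x[ord, ]; y <- y[ord]
  rec <- train_recipe(resample = resample_spec("none"), n_trees = 60,
                      decision_threshold = 0.5, seed = 10)
  tr <- 1:250; va <- 251:400
  lad <- forward_selection(rec, x[tr, ], y[tr], x[va, ], y[va])
  expect_equal(lad$feature[1], "perfect")
  expect_equal(nrow(lad), 3)
  expect_true(all(diff(order(lad$step)) == 1))

  lad1 <- forward_selection(rec, x[tr, ], y[tr], x[va, ], y[va],
                            candidates = "weak")
  expect_equal(nrow(lad1), 1)
  expect_error(forward_selection(rec, x[tr, ], y[tr], x[va, ], y[va],
                                 candidates = character()), "no candidates")
})

test_that("feature correlation is a proper correlation matrix with flags", {
  set.seed(65)
  x <- data.frame(a = rnorm(50), b = rnorm(50), flat = rep(2, 50))
  x$c <- x$a * 2 + rnorm(50, 0, 0.01)
  cm <- feature_correlation(x)
  expect_equal(diag(cm), c(a = 1, b = 1, flat = 1, c = 1))
  expect_equal(cm, t(cm))
  expect_gt(cm["a", "c"], 0.99)
  expect_equal(cm["flat", "a"], 0)
  expect_equal(attr(cm, "zero_variance"), "flat")
  expect_error(feature_correlation(x[1, ]), "at least 2")
})

test_that("overlapping antecedent windows correlate on a seasonal corpus", {
  cp <- small_corpus()
  cm <- feature_correlation(cp$features[, feature_names()])
  expect_gt(cm["dT30", "dT90"], 0)
  expect_gt(cm["dT90", "dT180"], 0)
  # anti-coupled humidity generator: temperature vs humidity negative
  expect_lt(cm["max_temp", "mean_humid"], 0)
})
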