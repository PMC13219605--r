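test_that("degenerate generator settings give a constant series", {
  p <- weather_params(n_cities = 1, years = 2, seasonal_amplitude = 0,
                      noise_sd = 0, mean_tmax_range = c(20, 20), seed = 1)
  s <- generate_city_series(p, 1)
  expect_true(all(abs(s$tmax - 20) < 1e-12))
  validate_city_series(s)
})

test_that("series generation is deterministic per (seed, city)", {
  p <- weather_params(n_cities = 3, years = 3, seed = 33)
  expect_identical(generate_city_series(p, 2), generate_city_series(p, 2))
  s1 <- generate_city_series(p, 1)
  s2 <- generate_city_series(p, 2)
  expect_false(isTRUE(all.equal(s1$tmax, s2$tmax)))
})

test_that("deseasonalised temperature recovers the AR(1) coefficient", {
  p <- weather_params(n_cities = 1, years = 10, ar1_coefficient = 0.7,
                      noise_sd = 2, seed = 77)
  s <- generate_city_series(p, 1)
  t_idx <- as.numeric(s$date - s$date[1])
  season <- fitted(lm(s$tmax ~ sin(2 * pi * t_idx / 365.25) +
                        cos(2 * pi * t_idx / 365.25)))
  a1 <- acf(s$tmax - season, plot = FALSE)$acf[2]
  expect_lt(abs(a1 - 0.7), 0.1)
})

test_that("humidity is clipped and anti-correlated with temperature", {
  p <- weather_params(n_cities = 6, years = 4, seed = 5)
  for (ci in 1:3) {
    s <- generate_city_series(p, ci)
    expect_true(all(s$rh >= 1 & s$rh <= 100))
    expect_lt(cor(s$tmax, s$rh), 0)
  }
})

test_that("label planting hits target prevalence without signal or threshold", {
  # pure-intercept shock model on many events: binomial check
  n <- 60000
  set.seed(90)
  events <- data.frame(event_id = sprintf("e%d", 1:n),
                       tmax = runif(n, 20, 30), rh_mean = runif(n, 30, 60))
  feats <- data.frame(dT180 = rnorm(n), dT30 = rnorm(n), mean_bmi = rnorm(n),
                      age_gradient = rnorm(n), mean_sdi = rnorm(n))
  mech <- lethality_mechanism(shock_weights = c(dT180 = 0), threshold_wbt = 35,
                              target_prevalence = 0.0078, seed = 4)
  lab <- plant_lethality(events, feats, mech)
  expect_equal(sum(lab$lethal == 1 & lab$mechanism == "Threshold", na.rm = TRUE), 0)
  frac <- mean(lab$lethal)
  expect_gt(frac, 0.0078 * 0.5)
  expect_lt(frac, 0.0078 * 1.5)
})

test_that("events above the wet-bulb cutoff are always lethal by Threshold", {
  events <- data.frame(event_id = "e1", tmax = 45, rh_mean = 70)  # WBT ~ 39
  feats <- data.frame(dT180 = 0, dT30 = 0, mean_bmi = 0,
                      age_gradient = 0, mean_sdi = 0)
  mech <- lethality_mechanism(threshold_wbt = 35, seed = 1)
  lab <- plant_lethality(events, feats, mech)
  expect_gt(lab$wbt, 35)
  expect_equal(lab$lethal, 1L)
  expect_equal(lab$mechanism, "Threshold")
  expect_error(plant_lethality(events, feats[c(1, 1), ], mech), "not aligned")
})

test_that("heavier dT180 weighting raises dT180 among shock-lethal events", {
  set.seed(91)
  n <- 20000
  events <- data.frame(event_id = sprintf("e%d", 1:n),
                       tmax = runif(n, 20, 30), rh_mean = runif(n, 30, 60))
  feats <- data.frame(dT180 = rnorm(n), dT30 = rnorm(n), mean_bmi = rnorm(n),
                      age_gradient = rnorm(n), mean_sdi = rnorm(n))
  mean_dt180 <- function(w) {
    mech <- lethality_mechanism(shock_weights = c(dT180 = w),
                                target_prevalence = 0.01, seed = 6)
    lab <- plant_lethality(events, feats, mech)
    mean(feats$dT180[lab$lethal == 1])
  }
  expect_gt(mean_dt180(3), mean_dt180(1.5))
})

test_that("corpus generation is reproducible and structurally sound", {
  cp <- small_corpus()
  cp2 <- generate_corpus(weather_params(n_cities = 24, years = 16, seed = 42),
                         lethality_mechanism(target_prevalence = 0.03, seed = 42))
  expect_identical(cp$events, cp2$events)
  expect_identical(cp$features, cp2$features)

  ev <- cp$events
  # every event has ten years of prior record in its city series
  for (city in unique(ev$city_id)) {
    d0 <- min(cp$weather$date[cp$weather$city_id == city])
    expect_true(all(ev$start_date[ev$city_id == city] - d0 >= 10 * 365))
  }
  # mechanism separability
  lethal <- ev[ev$lethal == 1, ]
  expect_true(all(lethal$wbt[lethal$mechanism == "Threshold"] > 35))
  expect_true(all(lethal$wbt[lethal$mechanism == "Shock"] <= 35))
  # realised prevalence within +-50% relative of target
  expect_gt(mean(ev$lethal), 0.03 * 0.5)
  expect_lt(mean(ev$lethal), 0.03 * 1.5)
})

test_that("an aseasonal corpus spreads events over the calendar", {
  p <- weather_params(n_cities = 10, years = 15, seasonal_amplitude = 0,
                      seed = 55)
  cp <- generate_corpus(p, lethality_mechanism(target_prevalence = 0.02))
  months <- as.POSIXlt(cp$events$start_date)$mon
  tab <- table(factor(months, levels = 0:11))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("zero-event settings raise a configuration error naming the settings", {
  p <- weather_params(n_cities = 1, years = 12, seasonal_amplitude = 0,
                      noise_sd = 0, mean_tmax_range = c(20, 20), seed = 2)
  expect_error(generate_corpus(p, lethality_mechanism()),
               "percentile|min_duration")
})

test_that("corpus CSV artefacts round-trip through plain text", {
  cp <- small_corpus()
  dir <- tempfile("corpus")
  paths <- write_corpus(cp, dir)
  expect_true(all(file.exists(paths)))
  ev <- read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(ev), nrow(cp$events))
  expect_equal(ev$lethal, cp$events$lethal)
  unlink(dir, recursive = TRUE)
})
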