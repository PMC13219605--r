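test_that("differentials match arithmetic on constructed series", {
  s <- make_series(400, tmax = rep(25, 400), rh = rep(60, 400))
  s$tmax[201:205] <- 35
  s$rh[201:205] <- 80
  ev <- make_event(s, s$date[201], s$date[205])
  expect_equal(temp_differential(s, ev, 30), 10)
  expect_equal(humid_differential(s, ev, 30), 20)

  # event equal to its antecedent mean has zero differential
  ev0 <- make_event(s, s$date[50], s$date[51])
  expect_equal(temp_differential(s, ev0, 30), 0)
  expect_equal(humid_differential(s, ev0, 30), 0)

  expect_error(temp_differential(s, ev0, 60), "window")
})

test_that("differentials and adaptive means agree with brute force on random series", {
  set.seed(7)
  s <- make_series(12 * 365 + 3, tmax = rnorm(12 * 365 + 3, 20, 6),
                   rh = runif(12 * 365 + 3, 20, 90))
  ev <- make_event(s, as.Date("2011-07-04"), as.Date("2011-07-08"))
  for (n in c(30, 90, 180)) {
    expect_equal(temp_differential(s, ev, n),
                 ev$tmax - brute_window_mean(s, ev$start_date, n, "tmax"),
                 tolerance = 1e-9)
    expect_equal(humid_differential(s, ev, n),
                 ev$rh_mean - brute_window_mean(s, ev$start_date, n, "rh"),
                 tolerance = 1e-9)
  }
  # brute-force double sum over the same calendar window in 10 years
  brute_adaptive <- function(col, n, m) {
    tot <- 0
    for (j in 0:(m - 1)) {
      d <- as.POSIXlt(ev$start_date); d$year <- d$year - j
      tot <- tot + brute_window_mean(s, as.Date(d), n, col) * n
    }
    tot / (m * n)
  }
  expect_equal(adaptive_temperature(s, ev, 30, 10), brute_adaptive("tmax", 30, 10),
               tolerance = 1e-9)
  expect_equal(adaptive_humidity(s, ev, 30, 10), brute_adaptive("rh", 30, 10),
               tolerance = 1e-9)
})

test_that("constant and periodic series give the forced adaptive values", {
  s <- make_series(11 * 365, tmax = rep(20, 11 * 365), rh = rep(55, 11 * 365))
  ev <- make_event(s, as.Date("2010-06-01"), as.Date("2010-06-02"))
  expect_equal(adaptive_temperature(s, ev, 30, 10), 20)
  expect_equal(adaptive_humidity(s, ev, 30, 10), 55)
  # fewer than the minimum complete years errors
  ev_early <- make_event(s, as.Date("2000-06-01"), as.Date("2000-06-02"))
  expect_error(adaptive_temperature(s, ev_early, 300, 10), "complete years")
})

test_that("temperature translation shifts levels but not differentials", {
  set.seed(8)
  nd <- 11 * 365
  s <- make_series(nd, tmax = rnorm(nd, 18, 5), rh = runif(nd, 30, 80))
  ev <- make_event(s, as.Date("2009-08-01"), as.Date("2009-08-03"))
  s2 <- s; s2$tmax <- s$tmax + 7.5
  ev2 <- make_event(s2, ev$start_date, ev$end_date)
  for (n in c(30, 180))
    expect_equal(temp_differential(s2, ev2, n), temp_differential(s, ev, n),
                 tolerance = 1e-9)
  expect_equal(adaptive_temperature(s2, ev2, 30, 10),
               adaptive_temperature(s, ev, 30, 10) + 7.5, tolerance = 1e-9)
  expect_equal(ev2$tmax, ev$tmax + 7.5)
})

test_that("dT180 of a pure seasonal cycle peaks at the seasonal maximum", {
  nd <- 12 * 366
  start <- as.Date("2000-01-01")
  t_idx <- seq_len(nd) - 1
  s <- make_series(nd, tmax = 20 + 10 * sin(2 * pi * t_idx / 365.25))
  dts <- vapply(seq(365 * 11, 365 * 11 + 364, by = 14), function(i) {
    ev <- make_event(s, s$date[i], s$date[i + 1])
    temp_differential(s, ev, 180)
  }, numeric(1))
  days <- seq(365 * 11, 365 * 11 + 364, by = 14)
  # the largest differential occurs for events near the sinusoid peak: the
  # analytic maximum of sin(t) - mean over the prior half-period leads the
  # seasonal peak by ~5 weeks, encoding the cold-winter-to-hot-summer swing
  peak_day <- days[which.max(dts)] %% 365.25
  expect_lt(abs(peak_day - 365.25 / 4), 45)
  # and the differential near the seasonal peak dwarfs the one at the trough
  expect_gt(max(dts), 5)
  trough_day <- days[which.min(dts)] %% 365.25
  expect_lt(abs(trough_day - 3 * 365.25 / 4), 45)
})

test_that("batch feature building composes the per-event operations exactly", {
  cp <- small_corpus()
  ev <- cp$events
  set.seed(9)
  pick <- sample(nrow(ev), 12)
  for (i in pick) {
    s <- cp$weather[cp$weather$city_id == ev$city_id[i], ]
    fv <- build_feature_vector(ev[i, ], s, cp$demographics)
    expect_equal(unlist(fv), unlist(cp$features[i, feature_names()]),
                 tolerance = 1e-9, info = ev$event_id[i])
  }
  expect_identical(names(cp$features), c("event_id", feature_names()))
  expect_true(all(is.finite(as.matrix(cp$features[, feature_names()]))))
})
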