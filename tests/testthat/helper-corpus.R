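# Shared fixtures, built in code and memoised for the session.

.fixtures <- new.env(parent = emptyenv())

# A small but pipeline-complete corpus: enough cities/years that every
# partition holds both classes.
small_corpus <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_corpus(
      weather_params(n_cities = 24, years = 16, seed = 42),
      lethality_mechanism(target_prevalence = 0.03, seed = 42))
  }
  .fixtures$small
}

# A deterministic constructed city series: linear dates, arbitrary values.
make_series <- function(ndays, tmax, rh = rep(50, ndays),
                        wind = rep(3, ndays), start = as.Date("2000-01-01"),
                        city = "city_001", country = "country_001") {
  data.frame(city_id = city, country_id = country,
             date = seq(start, by = "day", length.out = ndays),
             tmax = tmax, rh = rh, wind = wind, stringsAsFactors = FALSE)
}

make_event <- function(series, start, end) {
  sel <- series$date >= start & series$date <= end
  data.frame(event_id = "ev_test", city_id = series$city_id[1],
             country_id = series$country_id[1],
             start_date = as.Date(start), end_date = as.Date(end),
             duration = sum(sel),
             tmax = max(series$tmax[sel]), rh_mean = mean(series$rh[sel]),
             wind_mean = mean(series$wind[sel]), stringsAsFactors = FALSE)
}

# brute-force mean of column over the n days strictly before `start`
brute_window_mean <- function(series, start, n, col) {
  days <- seq(as.Date(start) - n, as.Date(start) - 1, by = "day")
  mean(series[[col]][match(days, series$date)])
}
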