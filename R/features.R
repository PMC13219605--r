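#' Canonical order of the 15 model inputs
#'
#' Event meteorology (`max_temp`, `mean_humid`, `mean_wind`), population
#' descriptors (`mean_bmi`, `mean_age`, `age_gradient`, `mean_sdi`),
#' antecedent temperature differentials over 30/90/180 days (`dT30`, `dT90`,
#' `dT180`), the multi-year adaptive temperature (`adaptive_temp`), the
#' corresponding humidity differentials (`dH30`, `dH90`, `dH180`) and
#' adaptive humidity (`adaptive_humid`).  This ordering is used for model
#' feature order and tie-breaking in forward selection.
#'
#' @return character vector of length 15.
#' @export
feature_names <- function() {
  c("max_temp", "mean_humid", "mean_wind",
    "mean_bmi", "mean_age", "age_gradient", "mean_sdi",
    "dT30", "dT90", "dT180", "adaptive_temp",
    "dH30", "dH90", "dH180", "adaptive_humid")
}

# mean of a pre-event window [start - n, start - 1] of column `col`;
# errors if the window is not fully covered by the series
antecedent_window_mean <- function(series, start_date, n, col) {
  i1 <- as.integer(start_date - series$date[1])  # index of start_date - 1 is i1
  if (i1 - n < 0 || i1 > nrow(series))
    stop_config("antecedent window of %d days before %s not covered by series (%s..%s)",
                n, format(start_date), format(series$date[1]),
                format(series$date[nrow(series)]))
  mean(series[[col]][(i1 - n + 1L):i1])
}

#' Antecedent temperature differential
#'
#' The event's maximum temperature minus the mean daily maximum temperature
#' over the `n` calendar days strictly before the event start.  Positive
#' values mean the heatwave peak stands above recent conditions; the 180-day
#' version is large for summer events following a cold winter.
#'
#' @param series city series covering the `n` days before the event.
#' @param event one event row as returned by [extract_events()].
#' @param n antecedent window length in days (30, 90 or 180 in the model).
#' @return temperature differential, degrees C.
#' @export
temp_differential <- function(series, event, n) {
  event$tmax - antecedent_window_mean(series, event$start_date, n, "tmax")
}

#' Antecedent humidity differential
#'
#' As [temp_differential()] but for relative humidity: the event's mean
#' relative humidity minus the mean humidity over the `n` days before the
#' event start.
#'
#' @inheritParams temp_differential
#' @return humidity differential, percentage points.
#' @export
humid_differential <- function(series, event, n) {
  event$rh_mean - antecedent_window_mean(series, event$start_date, n, "rh")
}

# indices and availability for the m yearly pre-event windows; returns a
# list(anchors = integer end indices, usable = logical)
adaptive_anchor_index <- function(series, start_date, n, m) {
  anchors <- shift_years(rep(start_date, m), seq_len(m) - 1L)
  i1 <- as.integer(anchors - series$date[1])
  usable <- i1 - n >= 0 & i1 <= nrow(series)
  list(i1 = i1, usable = usable)
}

adaptive_mean <- function(series, event, n, m, col, min_years = 3) {
  a <- adaptive_anchor_index(series, event$start_date, n, m)
  k <- sum(a$usable)
  if (k < min_years)
    stop_config("adaptive window needs at least %d complete years, only %d available before %s",
                min_years, k, format(event$start_date))
  x <- series[[col]]
  s <- vapply(a$i1[a$usable],
              function(i1) sum(x[(i1 - n + 1L):i1]), numeric(1))
  sum(s) / (k * n)
}

#' Adaptive temperature
#'
#' The mean of the daily maximum temperature over the same `n`-day pre-event
#' calendar window in the event year and each of the preceding `m - 1` years
#' (for an event at the end of January this is the average over that January
#' and the previous `m - 1` Januaries).  A proxy for the temperature a
#' population is acclimatised to at that point of the seasonal cycle.  If
#' fewer than `m` years of history exist, all available complete years are
#' used, with a minimum of `min_years`.
#'
#' @inheritParams temp_differential
#' @param m number of years averaged over (default 10).
#' @param min_years minimum acceptable number of complete years (default 3).
#' @return adaptive temperature, degrees C.
#' @export
adaptive_temperature <- function(series, event, n, m = 10, min_years = 3) {
  adaptive_mean(series, event, n, m, "tmax", min_years)
}

#' Adaptive humidity
#'
#' As [adaptive_temperature()] but averaging daily mean relative humidity; a
#' proxy for a population's long-run acclimatisation to local humidity.
#'
#' @inheritParams adaptive_temperature
#' @return adaptive humidity, percent.
#' @export
adaptive_humidity <- function(series, event, n, m = 10, min_years = 3) {
  adaptive_mean(series, event, n, m, "rh", min_years)
}

#' Assemble the 15-feature input vector for one event
#'
#' Combines the event meteorology, demographic compressions for the event's
#' country (nearest available year, ties to the earlier year) and the
#' antecedent / adaptive variables into the canonical 15-field feature
#' vector.
#'
#' @param event one event row.
#' @param series the event city's series.
#' @param demographics demographics table (see [generate_demographics()] for
#'   the schema).
#' @param n_windows antecedent window lengths in days (default 30, 90, 180).
#' @param n_adaptive window length for the adaptive variables (default 30).
#' @param m years for the adaptive variables (default 10).
#' @return one-row data frame with columns `feature_names()`.
#' @export
build_feature_vector <- function(event, series, demographics,
                                 n_windows = c(30, 90, 180),
                                 n_adaptive = 30, m = 10) {
  if (event$city_id != series$city_id[1])
    stop_config("event %s is not from city %s", event$event_id, series$city_id[1])
  demo <- demographic_features(demographics)
  row <- match_demo_year(demo, event$country_id,
                         as.POSIXlt(event$start_date)$year + 1900L)
  out <- data.frame(
    max_temp = event$tmax, mean_humid = event$rh_mean, mean_wind = event$wind_mean,
    mean_bmi = row$mean_bmi, mean_age = row$mean_age,
    age_gradient = row$age_gradient, mean_sdi = row$sdi,
    dT30 = NA_real_, dT90 = NA_real_, dT180 = NA_real_,
    adaptive_temp = adaptive_temperature(series, event, n_adaptive, m),
    dH30 = NA_real_, dH90 = NA_real_, dH180 = NA_real_,
    adaptive_humid = adaptive_humidity(series, event, n_adaptive, m)
  )
  for (i in seq_along(n_windows)) {
    out[[paste0("dT", n_windows[i])]] <- temp_differential(series, event, n_windows[i])
    out[[paste0("dH", n_windows[i])]] <- humid_differential(series, event, n_windows[i])
  }
  out[, feature_names(), drop = FALSE]
}

# nearest-year demographic match, ties to the earlier year
match_demo_year <- function(demo, country, year) {
  rows <- demo[demo$country_id == country, , drop = FALSE]
  if (!nrow(rows))
    stop_config("no demographics for country %s", country)
  d <- abs(rows$year - year)
  rows[order(d, rows$year), , drop = FALSE][1, , drop = FALSE]
}

#' Build the feature matrix for a whole event catalogue
#'
#' Vectorised equivalent of [build_feature_vector()] over many events and
#' cities, using per-city cumulative sums so each antecedent window mean is
#' O(1).  Events whose antecedent or adaptive windows are not covered by the
#' series raise an error naming the event.
#'
#' @param events event catalogue (rows as returned by [extract_events()],
#'   any number of cities).
#' @param weather daily weather for all cities: a data frame in city-series
#'   format with multiple `city_id` values.
#' @param demographics demographics table.
#' @inheritParams build_feature_vector
#' @return data frame with `event_id` plus the 15 feature columns.
#' @export
build_features <- function(events, weather, demographics,
                           n_windows = c(30, 90, 180),
                           n_adaptive = 30, m = 10, min_years = 3) {
  demo <- demographic_features(demographics)
  out <- matrix(NA_real_, nrow(events), length(feature_names()),
                dimnames = list(NULL, feature_names()))
  out[, "max_temp"] <- events$tmax
  out[, "mean_humid"] <- events$rh_mean
  out[, "mean_wind"] <- events$wind_mean

  # demographic join cached by (country, year)
  ev_year <- as.POSIXlt(events$start_date)$year + 1900L
  key <- paste(events$country_id, ev_year)
  ukey <- !duplicated(key)
  demo_rows <- do.call(rbind, Map(function(cn, yr) {
    match_demo_year(demo, cn, yr)[, c("mean_bmi", "mean_age", "age_gradient", "sdi")]
  }, events$country_id[ukey], ev_year[ukey]))
  rownames(demo_rows) <- key[ukey]
  dm <- demo_rows[key, , drop = FALSE]
  out[, "mean_bmi"] <- dm$mean_bmi
  out[, "mean_age"] <- dm$mean_age
  out[, "age_gradient"] <- dm$age_gradient
  out[, "mean_sdi"] <- dm$sdi

  for (city in unique(events$city_id)) {
    sel <- events$city_id == city
    ev <- events[sel, , drop = FALSE]
    s <- weather[weather$city_id == city, , drop = FALSE]
    if (!nrow(s)) stop_config("no weather series for city %s", city)
    d0 <- s$date[1]
    nd <- nrow(s)
    cs_t <- c(0, cumsum(s$tmax))
    cs_h <- c(0, cumsum(s$rh))
    i1 <- as.integer(ev$start_date - d0)  # cumsum index of day before start
    for (n in n_windows) {
      bad <- i1 - n < 0 | i1 > nd
      if (any(bad))
        stop_config("event %s lacks the %d-day antecedent window",
                    ev$event_id[which(bad)[1]], n)
      wt <- (cs_t[i1 + 1L] - cs_t[i1 - n + 1L]) / n
      wh <- (cs_h[i1 + 1L] - cs_h[i1 - n + 1L]) / n
      out[sel, paste0("dT", n)] <- ev$tmax - wt
      out[sel, paste0("dH", n)] <- ev$rh_mean - wh
    }
    # adaptive: m yearly anchors per event
    n <- n_adaptive
    sum_t <- sum_h <- numeric(nrow(ev))
    kyrs <- integer(nrow(ev))
    for (jy in 0:(m - 1L)) {
      aj <- as.integer(shift_years(ev$start_date, jy) - d0)
      ok <- aj - n >= 0 & aj <= nd
      sum_t[ok] <- sum_t[ok] + (cs_t[aj[ok] + 1L] - cs_t[aj[ok] - n + 1L])
      sum_h[ok] <- sum_h[ok] + (cs_h[aj[ok] + 1L] - cs_h[aj[ok] - n + 1L])
      kyrs <- kyrs + ok
    }
    if (any(kyrs < min_years))
      stop_config("event %s has only %d complete years for adaptive variables (need %d)",
                  ev$event_id[which(kyrs < min_years)[1]],
                  min(kyrs), min_years)
    out[sel, "adaptive_temp"] <- sum_t / (kyrs * n)
    out[sel, "adaptive_humid"] <- sum_h / (kyrs * n)
  }
  cbind(data.frame(event_id = events$event_id, stringsAsFactors = FALSE),
        as.data.frame(out))
}
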