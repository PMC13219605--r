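#' Validate a daily city weather series
#'
#' A city series is a data frame with one row per day and columns `city_id`,
#' `country_id`, `date` (class Date, strictly increasing, no gaps), `tmax`
#' (daily maximum temperature, degrees C), `rh` (mean relative humidity,
#' percent, in \[0, 100\]) and `wind` (mean windspeed, m/s).
#'
#' @param series data frame as described above, for a single city.
#' @return the series, invisibly, after validation.
#' @export
validate_city_series <- function(series) {
  need <- c("city_id", "country_id", "date", "tmax", "rh", "wind")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop_config("city series is missing columns: %s", paste(miss, collapse = ", "))
  if (length(unique(series$city_id)) != 1L)
    stop_config("a city series must contain exactly one city")
  if (!inherits(series$date, "Date"))
    stop_config("series$date must be of class Date")
  d <- as.integer(diff(series$date))
  if (length(d) && any(d != 1L))
    stop_config("series dates must be contiguous daily (gap near row %d)",
                which(d != 1L)[1] + 1L)
  if (any(series$rh < 0 | series$rh > 100))
    stop_config("relative humidity outside [0, 100]")
  invisible(series)
}

#' Extract heatwave events from a daily series
#'
#' A heatwave is a maximal run of at least `min_duration` consecutive days
#' whose daily maximum temperature strictly exceeds the city's historical
#' percentile threshold (by default the 90th percentile of the full record).
#' Per-event summaries are the maximum temperature over the run, and the mean
#' relative humidity and mean windspeed over the run.
#'
#' @param series a validated city series (see [validate_city_series()]).
#' @param percentile fraction in (0, 1); historical quantile of daily `tmax`
#'   defining the exceedance threshold. Default 0.90.
#' @param min_duration minimum run length in days. Default 2.
#' @param calendar_percentile logical; if `TRUE`, the threshold varies by day
#'   of year (quantile of each calendar day's historical values) instead of a
#'   single full-record quantile. Default `FALSE`.
#' @return data frame with one row per event: `event_id`, `city_id`,
#'   `country_id`, `start_date`, `end_date` (inclusive), `duration` (days),
#'   `tmax` (max over event), `rh_mean`, `wind_mean`.
#' @export
extract_events <- function(series, percentile = 0.90, min_duration = 2,
                           calendar_percentile = FALSE) {
  validate_city_series(series)
  if (nrow(series) < 365)
    stop_config("extract_events: series shorter than one year (%d days)",
                nrow(series))
  if (percentile <= 0 || percentile >= 1)
    stop_config("extract_events: percentile must be in (0, 1)")
  if (calendar_percentile) {
    doy <- as.POSIXlt(series$date)$yday
    thr_by_doy <- vapply(split(series$tmax, doy), stats::quantile,
                         numeric(1), probs = percentile, names = FALSE)
    above <- series$tmax > thr_by_doy[as.character(doy)]
  } else {
    thr <- stats::quantile(series$tmax, percentile, names = FALSE)
    above <- series$tmax > thr
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  starts <- starts[keep]
  ends <- ends[keep]
  if (!length(starts)) {
    return(data.frame(event_id = character(), city_id = character(),
                      country_id = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      duration = integer(), tmax = numeric(),
                      rh_mean = numeric(), wind_mean = numeric(),
                      stringsAsFactors = FALSE))
  }
  city <- as.character(series$city_id[1])
  data.frame(
    event_id = sprintf("%s_e%04d", city, seq_along(starts)),
    city_id = city,
    country_id = as.character(series$country_id[1]),
    start_date = series$date[starts],
    end_date = series$date[ends],
    duration = ends - starts + 1L,
    tmax = vapply(seq_along(starts),
                  function(i) max(series$tmax[starts[i]:ends[i]]), numeric(1)),
    rh_mean = vapply(seq_along(starts),
                     function(i) mean(series$rh[starts[i]:ends[i]]), numeric(1)),
    wind_mean = vapply(seq_along(starts),
                       function(i) mean(series$wind[starts[i]:ends[i]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}
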