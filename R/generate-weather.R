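#' Parameters for the synthetic multi-city weather generator
#'
#' The generator produces daily maximum temperature as a sinusoidal seasonal
#' cycle plus AR(1) Gaussian noise, relative humidity as a seasonal mean
#' anti-coupled to the temperature anomaly (hot spells are drier), and
#' windspeed as white noise.  Per-city mean temperatures are drawn uniformly
#' from `mean_tmax_range` so the corpus spans cool-temperate to hot cities.
#'
#' @param n_cities number of cities (study scale: 140).
#' @param years years of daily record per city (study scale: 35); must be
#'   at least 2 so the adaptive variables have history.
#' @param start_year first calendar year of the record.
#' @param mean_tmax_range range (degrees C) from which each city's annual
#'   mean daily maximum temperature is drawn.
#' @param seasonal_amplitude amplitude of the seasonal cycle, degrees C.
#' @param seasonal_phase phase shift in days (seasonal peak near
#'   `phase + 91` days into the year).
#' @param ar1_coefficient lag-1 autoregression of the temperature anomaly,
#'   in \[0, 1).
#' @param noise_sd innovation standard deviation of the AR(1) anomaly,
#'   degrees C.
#' @param rh_mean,rh_amplitude seasonal mean and amplitude of relative
#'   humidity, percent (humidity peaks half a year out of phase with
#'   temperature).
#' @param rh_temp_coupling percentage points of humidity per degree C of
#'   temperature anomaly; negative means hot days are drier.
#' @param rh_noise_sd innovation sd of the humidity noise, percent.
#' @param wind_mean,wind_sd daily windspeed mean and sd, m/s.
#' @param seed integer root seed for the weather substream.
#' @return object of class `weather_params`.
#' @export
weather_params <- function(n_cities = 140, years = 35, start_year = 1980,
                           mean_tmax_range = c(12, 32),
                           seasonal_amplitude = 10, seasonal_phase = 0,
                           ar1_coefficient = 0.7, noise_sd = 2,
                           rh_mean = 65, rh_amplitude = 10,
                           rh_temp_coupling = -1.5, rh_noise_sd = 8,
                           wind_mean = 3, wind_sd = 1, seed = 1L) {
  p <- list(n_cities = n_cities, years = years, start_year = start_year,
            mean_tmax_range = mean_tmax_range,
            seasonal_amplitude = seasonal_amplitude,
            seasonal_phase = seasonal_phase,
            ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
            rh_mean = rh_mean, rh_amplitude = rh_amplitude,
            rh_temp_coupling = rh_temp_coupling, rh_noise_sd = rh_noise_sd,
            wind_mean = wind_mean, wind_sd = wind_sd, seed = as.integer(seed))
  if (p$years < 2)
    stop_config("weather_params: years must be >= 2 (adaptive variables need history)")
  if (p$ar1_coefficient < 0 || p$ar1_coefficient >= 1)
    stop_config("weather_params: ar1_coefficient must be in [0, 1)")
  if (p$n_cities < 1) stop_config("weather_params: n_cities must be >= 1")
  class(p) <- "weather_params"
  p
}

#' Generate one city's daily weather series
#'
#' Deterministic given `(params$seed, city_index)`: every city draws from its
#' own substream, so regenerating city k alone reproduces the corpus city
#' exactly.
#'
#' @param params a [weather_params()] object.
#' @param city_index positive integer identifying the city.
#' @param country_id country identifier attached to the series (defaults to
#'   one country per four cities).
#' @return city-series data frame (see [validate_city_series()]).
#' @export
generate_city_series <- function(params, city_index,
                                 country_id = sprintf("country_%03d",
                                                      ceiling(city_index / 4))) {
  stopifnot(inherits(params, "weather_params"))
  if (params$years < 2)
    stop_config("generate_city_series: years must be >= 2")
  seeds <- substream_seeds(params$seed, c("weather", "demographics", "labels"))
  set.seed((seeds[["weather"]] + 7919L * as.integer(city_index)) %%
             .Machine$integer.max)
  d0 <- as.Date(sprintf("%d-01-01", params$start_year))
  d1 <- as.Date(sprintf("%d-12-31", params$start_year + params$years - 1L))
  dates <- seq(d0, d1, by = "day")
  nd <- length(dates)
  t_idx <- as.numeric(dates - d0)
  city_mean <- stats::runif(1, params$mean_tmax_range[1], params$mean_tmax_range[2])
  season <- params$seasonal_amplitude *
    sin(2 * pi * (t_idx - params$seasonal_phase) / 365.25)
  anom <- as.numeric(stats::filter(stats::rnorm(nd, 0, params$noise_sd),
                                   params$ar1_coefficient, method = "recursive"))
  tmax <- city_mean + season + anom
  # humidity anti-couples to both the within-city anomaly and the city's
  # position in the corpus temperature range (hot cities are drier),
  # reproducing the negative temperature-humidity correlation of the study
  # geometry and keeping wet-bulb temperatures above 35 C vanishingly rare
  rh <- params$rh_mean -
    params$rh_amplitude * sin(2 * pi * (t_idx - params$seasonal_phase) / 365.25) +
    params$rh_temp_coupling * (anom + city_mean - mean(params$mean_tmax_range)) +
    stats::rnorm(nd, 0, params$rh_noise_sd)
  rh <- pmin(100, pmax(1, rh))
  wind <- pmax(0.1, stats::rnorm(nd, params$wind_mean, params$wind_sd))
  data.frame(city_id = sprintf("city_%03d", as.integer(city_index)),
             country_id = country_id,
             date = dates, tmax = tmax, rh = rh, wind = wind,
             stringsAsFactors = FALSE)
}
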