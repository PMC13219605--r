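#' Generate a full synthetic study corpus
#'
#' Runs the generator end to end: per-city weather series, country-year
#' demographics, heatwave extraction, feature assembly and two-mechanism
#' label planting.  Only events with at least `history_years` of prior record
#' are kept, so every event carries complete antecedent and adaptive windows.
#'
#' @param weather a [weather_params()] object.
#' @param mech a [lethality_mechanism()] object.
#' @param percentile,min_duration heatwave extraction settings
#'   (see [extract_events()]).
#' @param n_windows,n_adaptive,m feature settings (see [build_features()]).
#' @param history_years burn-in years at the start of each series from which
#'   no events are taken (default `m`, so adaptive variables never truncate).
#' @param cities_per_country cities sharing one demographic record
#'   (default 4).
#' @return object of class `heat_corpus`: a list with `weather` (daily series
#'   for all cities), `demographics`, `events` (labelled catalogue with `wbt`,
#'   `lethal`, `mechanism`), `features` (event_id + 15 columns, aligned with
#'   `events`) and `provenance` (generator settings and seeds).
#' @export
generate_corpus <- function(weather, mech,
                            percentile = 0.90, min_duration = 2,
                            n_windows = c(30, 90, 180), n_adaptive = 30,
                            m = 10, history_years = m,
                            cities_per_country = 4) {
  stopifnot(inherits(weather, "weather_params"),
            inherits(mech, "lethality_mechanism"))
  seeds <- substream_seeds(weather$seed, c("weather", "demographics", "labels"))
  n_countries <- ceiling(weather$n_cities / cities_per_country)
  demographics <- generate_demographics(
    n_countries, seed = seeds[["demographics"]],
    years = weather$start_year:(weather$start_year + weather$years - 1L))

  series_list <- vector("list", weather$n_cities)
  events_list <- vector("list", weather$n_cities)
  for (ci in seq_len(weather$n_cities)) {
    s <- generate_city_series(
      weather, ci,
      country_id = sprintf("country_%03d", ceiling(ci / cities_per_country)))
    ev <- extract_events(s, percentile = percentile, min_duration = min_duration)
    cutoff <- s$date[1] + round(history_years * 365.25)
    ev <- ev[ev$start_date >= cutoff, , drop = FALSE]
    series_list[[ci]] <- s
    events_list[[ci]] <- ev
  }
  weather_tbl <- do.call(rbind, series_list)
  events <- do.call(rbind, events_list)
  if (is.null(events) || !nrow(events))
    stop_config(paste0("generate_corpus: no events extracted ",
                       "(percentile = %.2f, min_duration = %d); ",
                       "lower the percentile or min_duration"),
                percentile, min_duration)
  rownames(events) <- NULL
  events$event_id <- sprintf("ev_%06d", seq_len(nrow(events)))

  features <- build_features(events, weather_tbl, demographics,
                             n_windows = n_windows, n_adaptive = n_adaptive,
                             m = m)
  mech_seeded <- mech
  mech_seeded$seed <- as.integer(seeds[["labels"]])
  events <- plant_lethality(events, features, mech_seeded)

  structure(list(
    weather = weather_tbl,
    demographics = demographics,
    events = events,
    features = features,
    provenance = list(weather = unclass(weather), mechanism = unclass(mech),
                      extraction = list(percentile = percentile,
                                        min_duration = min_duration,
                                        n_windows = n_windows,
                                        n_adaptive = n_adaptive, m = m,
                                        history_years = history_years,
                                        cities_per_country = cities_per_country),
                      substream_seeds = seeds,
                      shock_intercept = attr(events, "shock_intercept"))
  ), class = "heat_corpus")
}

#' @export
print.heat_corpus <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<heat_corpus> %d cities, %d days/city, %d events (%.3f%% lethal)\n",
              length(unique(x$weather$city_id)),
              sum(x$weather$city_id == x$weather$city_id[1]),
              nrow(ev), 100 * mean(ev$lethal)))
  mech <- table(ev$mechanism[ev$lethal == 1])
  if (length(mech))
    cat("  lethal mechanisms:",
        paste(sprintf("%s=%d", names(mech), mech), collapse = ", "), "\n")
  invisible(x)
}

#' Write corpus artefacts as plain-text CSV
#'
#' Writes `series.csv`, `demographics.csv`, `events.csv` and `features.csv`
#' under `dir`.
#'
#' @param corpus a `heat_corpus`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "heat_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("series.csv", "demographics.csv",
                            "events.csv", "features.csv"))
  utils::write.csv(corpus$weather, paths[1], row.names = FALSE)
  utils::write.csv(corpus$demographics, paths[2], row.names = FALSE)
  utils::write.csv(corpus$events, paths[3], row.names = FALSE)
  utils::write.csv(corpus$features, paths[4], row.names = FALSE)
  invisible(paths)
}
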