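#' Assign the Shock/Threshold lethal-heatwave taxonomy
#'
#' Lethal heatwaves split into two impact mechanisms: *Shock* heatwaves,
#' whose absolute conditions are modest but whose thermo-temporal
#' differentials from the local acclimation point trigger lethal stress
#' responses; and *Threshold* heatwaves, whose combined heat and humidity
#' exceed the body's capacity to dissipate heat.  Lethal events below a
#' wet-bulb temperature of `shock_cutoff` (default 25 degrees C) are almost
#' certainly Shock heatwaves; lethal events at or above it are labelled
#' Threshold (or `Indeterminate` within \[25, 35) when
#' `indeterminate_band = TRUE`).  Nonlethal events are labelled `NotLethal`.
#'
#' @param events event rows with `tmax` and `rh_mean`.
#' @param lethal 0/1 labels, predicted or observed; defaults to
#'   `events$lethal`.
#' @param shock_cutoff wet-bulb cutoff in degrees C below which lethal events
#'   are Shock (default 25).
#' @param indeterminate_band if `TRUE`, lethal events with wet-bulb in
#'   \[shock_cutoff, 35) are labelled `Indeterminate` instead of Threshold.
#' @return data frame: `event_id` (if present), `taxonomy` (factor), `wbt`.
#' @export
assign_taxonomy <- function(events, lethal = events$lethal, shock_cutoff = 25,
                            indeterminate_band = FALSE) {
  wbt <- as.numeric(stull_wbt(events$tmax, events$rh_mean))
  lv <- c("NotLethal", "Shock", "Threshold",
          if (indeterminate_band) "Indeterminate")
  tax <- rep("NotLethal", nrow(events))
  is_lethal <- as.integer(lethal) == 1L
  tax[is_lethal & wbt < shock_cutoff] <- "Shock"
  tax[is_lethal & wbt >= shock_cutoff] <-
    if (indeterminate_band) "Indeterminate" else "Threshold"
  if (indeterminate_band)
    tax[is_lethal & wbt >= 35] <- "Threshold"
  out <- data.frame(taxonomy = factor(tax, levels = lv), wbt = wbt,
                    stringsAsFactors = FALSE)
  if (!is.null(events$event_id))
    out <- cbind(data.frame(event_id = events$event_id,
                            stringsAsFactors = FALSE), out)
  out
}
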