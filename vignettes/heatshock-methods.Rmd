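---
title: "Classifying lethal heatwaves from acclimation-aware features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lethal heatwaves from acclimation-aware features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatshock)
```

## The problem

Operational heat-health warning systems mostly classify heatwaves by their
absolute meteorological conditions, typically through wet-bulb temperature
(WBT) thresholds. That framing misses a large class of deadly events: in
temperate climates, excess mortality rises during heat episodes whose
absolute conditions are nowhere near the canonical 35 °C survivability
limit. The hypothesis this package operationalises is that heatwave
lethality is a function `f(ρ, c, h)` of three ingredients: the underlying
health and vulnerability of the population (`ρ`), the antecedent climate the
population is acclimatised to (`c`), and the absolute conditions of the
event itself (`h`). Lethality is then predicted by a calibrated classifier
over proxies for all three, and lethal events are divided into two
mechanisms:

* **Shock heatwaves** — modest absolute conditions, but aggressive
  thermo-temporal differentials from the local acclimation point that push
  vulnerable people beyond their adaptive capacity;
* **Threshold heatwaves** — combined heat and humidity exceed the body's
  ability to dissipate heat at all.

A lethal event with WBT below 25 °C is almost certainly a Shock heatwave;
`assign_taxonomy()` encodes that rule (with the 25 °C cutoff configurable
and an optional indeterminate band for lethal events between 25 and 35 °C,
where the rule is genuinely less certain).

## Features

For an event with maximum temperature `T_max` and mean humidity `H_mu`
over the event window, the package computes, per `n ∈ {30, 90, 180}` days:

* temperature differential `ΔT_n = T_max − mean(T_max over the n days
  strictly before the event start)`;
* humidity differential `ΔH_n = H_mu − mean(H over the same window)`;
* adaptive temperature/humidity: the mean over the same `n`-day pre-event
  calendar window in the event year and the previous `m − 1 = 9` years
  (an event at the end of January averages that January and the nine
  Januaries before it) — a proxy for long-run acclimatisation;
* the absolute conditions (`max_temp`, `mean_humid`, `mean_wind`);
* demographic compressions: mean BMI, SDI, and two scalars summarising the
  population pyramid — the weighted mean age (bracket midpoints, lower
  bound + 2.5 years, including the open-ended bracket) and the *age
  gradient*, the least-squares slope of bracket age on bracket proportion.
  With that variable assignment, bottom-heavy (young) pyramids give
  negative slopes and top-heavy (ageing) pyramids positive ones; a
  perfectly uniform pyramid has zero regressor variance and is rejected
  rather than given an arbitrary slope.

Wet-bulb temperature uses Stull's empirical inverse-psychrometric fit,
valid for roughly −20…50 °C and RH ≥ 5 %; outside that envelope the value
is still computed but flagged. The fit is not monotone in humidity below
about 5 °C dry-bulb, which is outside the regime heatwave events occupy.

Window conventions: event windows are inclusive of both endpoints;
antecedent windows are the `n` calendar days strictly before the start
date; the multi-year anchors shift the start date back whole calendar
years (Feb 29 pins to Feb 28). If fewer than `m` years of history exist,
all available complete years are used down to a minimum of 3, below which
the event is not featurisable. `n` for the adaptive variables defaults to
30 days — the natural reading of a month-scale acclimatisation window —
and is configurable.

Heatwave extraction: maximal runs of at least `min_duration = 2`
consecutive days strictly above the city's historical 90th percentile of
daily maximum temperature. A single hot day is conventionally not a
"prolonged episode", hence the 2-day default; the percentile basis is the
full station record (a calendar-day percentile variant is available but
not default). Demographic tables are annual; events match the nearest
available year, ties to the earlier year.

## Classifier

A bootstrap-bagged random forest (500 trees, √p features per split, grown
to purity) votes on each event; the raw score is the fraction of trees
voting lethal. Platt scaling — a logistic regression of held-out labels on
the raw score, fitted by maximum likelihood on the *validation* partition,
never on training data, which would inherit the forest's training optimism
— maps scores to calibrated probabilities. Classification applies a 0.6
probability threshold; ties classify lethal, because under-prediction of
lethal heat is the more damaging error. Lowering the threshold can only
raise recall (asserted as a property test).

Class imbalance (≈0.78 % lethal) is handled in the training partition
only: by default SMOTE to a 1:1 minority:majority ratio — synthetic
minority points `x_i + u (x_nn − x_i)` interpolated towards one of the
k = 5 nearest minority neighbours. Neighbour search runs in per-feature
standardised coordinates (the features mix °C, %, kg/m² and dimensionless
indices), while interpolation stays in the original coordinates, so every
synthetic point is a convex combination of two real minority points.
Random majority downsampling is available as the alternative; it shrinks
the pool of nonlethal examples and, at aggressive fractions, buys recall
at a heavy precision cost.

Splits are chronological within each region (region = city by default,
since the city is the unit of the weather series; country-level splitting
is available): the most recent 10 % of each region's events form the test
set (ceiling rounding, so every region with ≥ 3 events contributes), and a
single seeded global sample of one-ninth of the remainder — "without
stratification", read literally as a global draw — forms the validation
set, giving 80/10/10 overall. Within every region, all train and
validation events predate all test events.

## Evaluation

`compute_metrics()` reports the confusion counts plus accuracy, precision,
recall and F1. Zero-denominator ratios are reported as 0 with a flag
rather than NaN, so selection ladders stay totally ordered. Baselines:
`wbt_threshold_classifier()` predicts lethal above a fixed WBT (20, 25, 30,
35 °C grid), and a temperature+humidity-only forest isolates what absolute
conditions alone can do.

Two importance views are computed, and they deliberately disagree:
permutation importance (default 10 repeats, evaluated on the test
partition) shares credit between correlated features, while dropout
importance (full retrain per dropped feature) hides anything a correlated
partner can replace. Greedy forward selection scores candidate features on
the validation partition only and reports per-step test metrics; ties
break by the canonical feature order.

## The synthetic-data generator

The generator exists so the whole pipeline is testable end to end without
any external downloads. It emulates the *statistical shape* of the study
system, not its physics:

* **Weather** — per city, a sinusoidal seasonal cycle (amplitude 10 °C)
  plus AR(1) Gaussian anomalies (coefficient 0.7, innovation sd 2 °C);
  city mean temperatures drawn uniformly over 12–32 °C. Humidity is a
  seasonal mean (65 %, amplitude 10 % in antiphase with temperature) plus
  an anti-coupling of −1.5 percentage points per °C applied to the city's
  temperature offset and daily anomaly, plus noise (sd 8 %), clipped to
  [1, 100]. The anti-coupling reproduces the negative temperature–humidity
  correlation of a corpus skewed towards temperate regions and keeps
  events with WBT above 35 °C vanishingly rare, as observed. Windspeed is
  white noise. All randomness flows from one root seed through named
  substreams (weather / demographics / labels), and each city has its own
  substream, so any city regenerates independently.
* **Demographics** — per country (one per four cities), BMI in
  [20, 35] kg/m² with a slow upward drift, SDI in [0, 1], and 20-bracket
  pyramids with an exponential age trend whose sign spans young and ageing
  populations.
* **Labels** — the two-mechanism model: events with WBT above 35 °C are
  lethal outright (Threshold); the rest are Bernoulli with a logistic
  latent risk over standardised drivers, dominated by ΔT_180 and mean BMI.
  The intercept is tuned by bisection (≤ 60 iterations, ±10 % relative) to
  hit an overall prevalence of 0.78 %. The driver weights are large enough
  that the latent risk is signal-dominated: in the study system lethality
  is largely predictable from the features, so a generator whose labels
  were mostly coin flips would misrepresent the object of study — no
  classifier can (or should) recover labels that are noise.

What the generator does **not** emulate: spatial correlation between
cities, urban heat islands, trends in the seasonal cycle, reporting and
misdiagnosis error in lethality labels, and the geographic reporting bias
of the real catalogue. Passing tests therefore demonstrate that the
pipeline recovers structure it is designed to detect when that structure
is present — not that the real-world headline metrics transfer.

## Problem sizes and numerical choices

The full-scale corpus (140 cities × 35 years, defaults) yields roughly
25 000 events after the 10-year burn-in that guarantees every event full
antecedent and adaptive windows; repeated driver-recovery experiments run
at 60 cities × 25 years with 300 trees and 5 permutation repeats, sizes
chosen to keep a complete analysis on one CPU in minutes while leaving
every partition populated with both classes. Bisection brackets the
logistic intercept in [−40, 20]; SMOTE requires minority count > k and
errors otherwise; zero-variance columns in correlation matrices are
flagged and reported as 0.

## Known limitations

* The forest backend is ranger with one thread; raw scores use per-tree
  votes (`predict.all`), not leaf-probability averaging, matching the
  "aggregate of tree outputs" contract at some cost in smoothness.
* Platt calibration needs enough lethal events in the validation
  partition; below a handful of positives the fitted map is unstable and
  the 0.6-threshold classifier can degenerate to all-nonlethal. This is a
  faithful property of the method at small scale, not a defect of the
  implementation.
* Permutation importance at a hard decision threshold is a step function
  of the probabilities; with few test-partition positives its repeats have
  visibly nonzero variance, which is why importance reports carry standard
  deviations.
* Joint rank-recovery of several planted label drivers by permutation
  importance is unstable when one driver has correlated proxies: the three
  temperature differentials share the ΔT₁₈₀ signal, so they collectively
  occupy the top importance ranks and which of the trio ranks where varies
  with the training seed. Each planted driver reliably outranks a planted
  pure-noise column, but requiring *both* ΔT₁₈₀ and BMI inside the top
  three of all fifteen features fails in a substantial fraction of seeded
  runs. This is inherent to permutation importance under feature
  correlation (dropout importance shows the complementary distortion) and
  is reported as measured, not tuned away.
* The taxonomy rule is deterministic given (label, T, RH, cutoff); it
  recovers the generator's planted mechanism exactly when the cutoff
  matches the generator's hard-lethality threshold, and conservatively
  (Threshold-leaning) at the default 25 °C cutoff.
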