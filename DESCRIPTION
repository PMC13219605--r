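Package: heatshock
Title: Classifying Lethal Heatwaves from Acclimation-Aware Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study what makes a heatwave lethal at population level.
    Extracts heatwave events from daily city weather series, derives
    thermo-temporal acclimation features (antecedent temperature and humidity
    differentials, multi-year adaptive temperature and humidity, Stull
    wet-bulb temperature) and sociodemographic compressions (mean age and
    age gradient of a population pyramid, mean BMI, Socio-Demographic Index),
    and trains a Platt-calibrated random-forest classifier of heatwave
    lethality under severe class imbalance (chronological region-wise splits,
    majority downsampling, SMOTE). Includes wet-bulb-temperature threshold
    baselines, permutation and dropout feature importance, greedy forward
    feature selection, a Shock/Threshold lethal-heatwave taxonomy, and a
    seeded synthetic-data generator emulating multi-city weather,
    demographics and rare lethal events so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
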