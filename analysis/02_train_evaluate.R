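#!/usr/bin/env Rscript
# Train the SMOTE + random-forest + Platt pipeline on the simulated corpus
# (chronological 80/10/10 split by city), evaluate on the test partition and
# compare against wet-bulb-temperature threshold baselines and a
# temperature+humidity-only model.  Writes results/metrics.json and
# results/split.csv.  Run analysis/01_simulate.R first.

library(heatshock)

events <- read.csv("results/corpus/events.csv", stringsAsFactors = FALSE)
events$start_date <- as.Date(events$start_date)
features <- read.csv("results/corpus/features.csv", stringsAsFactors = FALSE)
stopifnot(identical(events$event_id, features$event_id))
feats <- features[, feature_names()]

sp <- temporal_split(events, seed = 1)
idx <- split(seq_len(nrow(events)), sp$partition)
write.csv(sp, "results/split.csv", row.names = FALSE)

recipe <- train_recipe(seed = 1)  # SMOTE 1:1, 500 trees, threshold 0.6
model <- train_model(recipe, feats[idx$train, ], events$lethal[idx$train],
                     feats[idx$validation, ], events$lethal[idx$validation])

test_x <- feats[idx$test, ]
test_y <- events$lethal[idx$test]
metrics <- compute_metrics(test_y, classify(model, test_x))
message("full 15-feature model, test partition:")
print(metrics)

baselines <- lapply(c(20, 25, 30, 35), function(thr)
  wbt_threshold_classifier(events[idx$test, ], thr)$metrics)
names(baselines) <- paste0("wbt_", c(20, 25, 30, 35))
for (nm in names(baselines))
  message(sprintf("  %s baseline F1: %.3f", nm, baselines[[nm]]$f1))

th_model <- train_model(recipe, feats[idx$train, ], events$lethal[idx$train],
                        feats[idx$validation, ], events$lethal[idx$validation],
                        features = c("max_temp", "mean_humid"))
th_metrics <- compute_metrics(
  test_y, classify(th_model, test_x[, c("max_temp", "mean_humid")]))
message(sprintf("temperature+humidity-only model F1: %.3f", th_metrics$f1))

as_row <- function(m) m[c("accuracy", "precision", "recall", "f1")]
out <- c(list(full_model = as_row(metrics), temp_humid_only = as_row(th_metrics)),
         lapply(baselines, as_row))
jsonlite::write_json(out, "results/metrics.json", auto_unbox = TRUE, digits = 6)
message("written results/metrics.json")
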