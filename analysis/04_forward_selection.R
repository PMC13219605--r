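#!/usr/bin/env Rscript
# Greedy forward feature selection: build the model one predictor at a time,
# adding whichever remaining candidate maximises validation F1, and report
# per-step test metrics (the selection signal never touches test).  Also
# fits the two reference subsets: temperature+humidity only, and everything
# except temperature and humidity.  Writes results/ladder.csv.
# Heavier than the other drivers (15 + 14 + ... model fits; a full ladder
# takes on the order of an hour on one CPU).  An optional argument caps the
# number of steps: Rscript analysis/04_forward_selection.R 5

library(heatshock)

args <- commandArgs(trailingOnly = TRUE)
max_steps <- if (length(args)) as.integer(args[1]) else length(feature_names())

events <- read.csv("results/corpus/events.csv", stringsAsFactors = FALSE)
events$start_date <- as.Date(events$start_date)
features <- read.csv("results/corpus/features.csv", stringsAsFactors = FALSE)
feats <- features[, feature_names()]
sp <- read.csv("results/split.csv", stringsAsFactors = FALSE)
idx <- split(seq_len(nrow(events)), sp$partition)

recipe <- train_recipe(n_trees = 300, seed = 1)
ladder <- forward_selection(recipe,
                            feats[idx$train, ], events$lethal[idx$train],
                            feats[idx$validation, ], events$lethal[idx$validation],
                            feats[idx$test, ], events$lethal[idx$test],
                            max_steps = max_steps)
print(ladder[, c("step", "feature", "val_f1", "test_f1")])

no_abs <- setdiff(feature_names(), c("max_temp", "mean_humid"))
clf <- train_model(recipe, feats[idx$train, ], events$lethal[idx$train],
                   feats[idx$validation, ], events$lethal[idx$validation],
                   features = no_abs)
m <- compute_metrics(events$lethal[idx$test],
                     classify(clf, feats[idx$test, no_abs]))
message(sprintf("model without absolute conditions (13 features): F1 %.3f", m$f1))
extra <- data.frame(step = NA, feature = "all_but_max_temp_mean_humid",
                    val_f1 = NA, test_accuracy = m$accuracy,
                    test_precision = m$precision, test_recall = m$recall,
                    test_f1 = m$f1)
write.csv(rbind(ladder, extra), "results/ladder.csv", row.names = FALSE)
message("written results/ladder.csv")
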