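#!/usr/bin/env Rscript
# Assign the Shock/Threshold taxonomy to test-partition events, on both the
# observed labels and the model's predictions, and cross-tabulate against
# the generator's planted mechanism.  Writes results/taxonomy.csv.

library(heatshock)

events <- read.csv("results/corpus/events.csv", stringsAsFactors = FALSE)
events$start_date <- as.Date(events$start_date)
features <- read.csv("results/corpus/features.csv", stringsAsFactors = FALSE)
feats <- features[, feature_names()]
sp <- read.csv("results/split.csv", stringsAsFactors = FALSE)
idx <- split(seq_len(nrow(events)), sp$partition)

recipe <- train_recipe(seed = 1)
model <- train_model(recipe, feats[idx$train, ], events$lethal[idx$train],
                     feats[idx$validation, ], events$lethal[idx$validation])
pred <- classify(model, feats[idx$test, ])

test_ev <- events[idx$test, ]
obs <- assign_taxonomy(test_ev)                    # observed labels
prd <- assign_taxonomy(test_ev, lethal = pred)     # predicted labels
out <- data.frame(event_id = test_ev$event_id, wbt = round(obs$wbt, 2),
                  observed = as.character(obs$taxonomy),
                  predicted = as.character(prd$taxonomy),
                  planted_mechanism = test_ev$mechanism)
write.csv(out, "results/taxonomy.csv", row.names = FALSE)

message("observed taxonomy vs planted mechanism (lethal test events):")
print(table(out$observed[test_ev$lethal == 1],
            out$planted_mechanism[test_ev$lethal == 1], useNA = "ifany"))
message("written results/taxonomy.csv")
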