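#!/usr/bin/env Rscript
# Sensitivity analysis of the trained model: permutation importance and
# dropout (drop-column) importance on the test partition, plus the predictor
# correlation matrix.  Writes results/importance.csv and
# results/correlation.csv.  Run 01 and 02 first (02 for the split).

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

imp <- permutation_importance(model, feats[idx$test, ],
                              events$lethal[idx$test], n_repeats = 10, seed = 1)
message("permutation importance (top 5):")
print(head(imp[order(-imp$mean_decrease), ], 5))

di <- dropout_importance(recipe, feats[idx$train, ], events$lethal[idx$train],
                         feats[idx$validation, ], events$lethal[idx$validation],
                         feats[idx$test, ], events$lethal[idx$test])
both <- merge(imp, di, by = "feature")
write.csv(both, "results/importance.csv", row.names = FALSE)

cm <- feature_correlation(feats)
write.csv(round(cm, 4), "results/correlation.csv")
message("written results/importance.csv and results/correlation.csv")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  both$feature <- factor(both$feature,
                         levels = both$feature[order(both$mean_decrease)])
  p <- ggplot(both, aes(mean_decrease, feature)) +
    geom_col(fill = "firebrick") +
    geom_errorbarh(aes(xmin = mean_decrease - sd_decrease,
                       xmax = mean_decrease + sd_decrease), height = 0.3) +
    labs(x = "mean decrease in F1 under permutation", y = NULL) +
    theme_minimal()
  ggsave("results/importance.png", p, width = 6, height = 5, dpi = 120)
}
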