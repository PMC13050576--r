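#!/usr/bin/env Rscript
# Stage 4 — the eleven-algorithm benchmark on the selected features:
# grid search (small per-model grids) under 10-fold stratified CV scored
# by weighted F1, refit on the balanced training set, evaluated once on
# the untouched imbalanced test set at threshold 0.5. Writes
# results/leaderboard.csv and per-model confusion matrices.
#
# Usage: Rscript analysis/04_benchmark.R [--cv 10]
#   (expects results/train.csv, test.csv, selected_features.txt)

library(earlygdm)

args <- commandArgs(trailingOnly = TRUE)
cv <- if ("--cv" %in% args) as.integer(args[match("--cv", args) + 1]) else 10

train <- read.csv("results/train.csv")
test <- read.csv("results/test.csv")
selected <- readLines("results/selected_features.txt")

bench <- run_benchmark(train[, selected], train$gdm,
                       test[, selected], test$gdm,
                       cv_folds = cv, seed = 42)

write.csv(bench$leaderboard, "results/leaderboard.csv", row.names = FALSE)
confusions <- lapply(bench$rows, function(r)
  c(r$confusion, list(chosen = bench$fits[[r$model]]$best_params)))
jsonlite::write_json(confusions, "results/model_details.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat("leaderboard (weighted metrics on the held-out test set):\n")
print(bench$leaderboard, digits = 4)
best <- bench$leaderboard[1, ]
cat(sprintf("\nbest model: %s (weighted F1 %.4f, AUC-ROC %.4f)\n",
            best$model, best$f1, best$auc_roc))
cm <- bench$rows[[best$model]]$confusion
cat(sprintf("its confusion matrix: TN %d, FP %d, FN %d, TP %d\n",
            cm$tn, cm$fp, cm$fn, cm$tp))
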