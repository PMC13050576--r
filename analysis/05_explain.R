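#!/usr/bin/env Rscript
# Stage 5 — Kernel SHAP attribution of the best benchmark model: 100
# randomly sampled test instances as background, 50 stratified test
# instances explained (33 positive / 17 negative), 2,048 coalitions per
# instance. Writes the attribution matrix, the global mean-|contribution|
# ranking, a waterfall ledger for the highest-risk explained case, and
# simple plots.
#
# Usage: Rscript analysis/05_explain.R
#   (expects results/train.csv, test.csv, selected_features.txt,
#    leaderboard.csv)

library(earlygdm)

train <- read.csv("results/train.csv")
test <- read.csv("results/test.csv")
selected <- readLines("results/selected_features.txt")
best_name <- read.csv("results/leaderboard.csv")$model[1]

spec <- model_specs(seed = 42)[[best_name]]
tt <- tune_and_train(spec, train[, selected], train$gdm, cv_folds = 10,
                     seed = 42)

sets <- sample_explain_sets(test[, selected], test$gdm, n_background = 100,
                            class_counts = c(positive = 33, negative = 17),
                            seed = 42)
att <- attribute(tt$model, sets$background, sets$explain_x,
                 n_coalitions = 2048, seed = 42)

write.csv(data.frame(att$matrix), "results/attributions.csv", row.names = FALSE)
gi <- global_importance(att)
write.csv(gi, "results/shap_global_importance.csv", row.names = FALSE)

# waterfall for the explained case with the highest predicted risk
top_case <- which.max(att$prediction)
wf <- waterfall(att, top_case)
jsonlite::write_json(wf, "results/waterfall_top_case.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

cat(sprintf("explained %d instances; base value (expected prediction) %.3f\n",
            nrow(att$matrix), att$base_value))
cat(sprintf("additivity residual: max %.2e\n",
            max(abs(att$base_value + rowSums(att$matrix) - att$prediction))))
cat("\nglobal importance (mean |contribution|):\n")
print(gi, digits = 3)
cat(sprintf("\ntop-risk case: prediction %.3f from base %.3f; leading step %s (%+.3f)\n",
            wf$prediction, wf$base_value, wf$steps$feature[1],
            wf$steps$value[1]))

# convenience plots: global importance bars and the top-case waterfall
pdf("results/shap_plots.pdf", width = 7, height = 5)
op <- par(mar = c(5, 9, 2, 1))
barplot(rev(gi$mean_abs_contribution), names.arg = rev(gi$feature),
        horiz = TRUE, las = 1, col = "steelblue",
        xlab = "mean |contribution| to predicted probability",
        main = "Global attribution ranking")
par(op)
steps <- wf$steps
from <- c(wf$base_value, head(steps$cumulative, -1))
op <- par(mar = c(5, 9, 2, 1))
plot(NULL, xlim = range(c(from, steps$cumulative)),
     ylim = c(0.5, nrow(steps) + 0.5), yaxt = "n",
     xlab = "predicted probability", ylab = "",
     main = sprintf("Waterfall: base %.3f to prediction %.3f",
                    wf$base_value, wf$prediction))
axis(2, at = rev(seq_len(nrow(steps))), labels = steps$feature, las = 1)
segments(from, rev(seq_len(nrow(steps))), steps$cumulative,
         col = ifelse(steps$value >= 0, "firebrick", "steelblue"), lwd = 6)
abline(v = wf$base_value, lty = 2, col = "grey50")
par(op)
dev.off()
cat("wrote results/shap_plots.pdf\n")
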