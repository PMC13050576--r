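#!/usr/bin/env Rscript
# Stage 3 — consensus feature importance: runs the seven methods (random
# forest and extra-randomized-forest impurity, ANOVA F-score, mutual
# information, permutation importance, recursive elimination, absolute
# Pearson correlation) on the balanced training matrix, averages the
# normalized scores, and reports the per-feature rank SD. Writes
# results/consensus.csv and results/selected_features.txt (top 10).
#
# Usage: Rscript analysis/03_select.R   (expects results/train.csv)

library(earlygdm)

train <- read.csv("results/train.csv")
y <- train$gdm
x <- train[, setdiff(names(train), "gdm")]

vectors <- importance_ensemble(x, y, seed = 42)
consensus <- consensus_rank(vectors)
selected <- select_top_k(consensus, 10)

write.csv(consensus, "results/consensus.csv", row.names = FALSE)
writeLines(selected, "results/selected_features.txt")

cat("consensus ranking (top 10):\n")
print(consensus[1:10, c("feature", "average", "rank_sd")], digits = 3)
cat("\nmost stable high-importance features (low rank SD) anchor the panel;\n")
cat("selected for modelling:", paste(selected, collapse = ", "), "\n")
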