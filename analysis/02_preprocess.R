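#!/usr/bin/env Rscript
# Stage 2 — preprocessing: one-hot ethnicity (drop-first, African
# reference), zero-imputation of untested OGTT (three-state encoding),
# stratified 80/20 split (seed 42), train-fitted standardization of the
# continuous features, and SMOTE balancing of the training partition only.
# Writes results/train.csv, results/test.csv, results/scaling_params.csv
# and a class-count manifest.
#
# Usage: Rscript analysis/02_preprocess.R   (expects results/cohort.csv)

library(earlygdm)

cohort <- read.csv("results/cohort.csv")
cohort$ethnicity <- as.character(cohort$ethnicity)
prep <- preprocess_cohort(cohort)

write.csv(cbind(prep$train_x, gdm = prep$train_y), "results/train.csv",
          row.names = FALSE)
write.csv(cbind(prep$test_x, gdm = prep$test_y), "results/test.csv",
          row.names = FALSE)
write.csv(prep$scaling_params, "results/scaling_params.csv", row.names = FALSE)
jsonlite::write_json(
  list(counts = lapply(prep$counts, function(x) if (is.table(x)) as.list(x) else x),
       n_synthetic = sum(prep$smote$synthetic),
       split_seed = prep$split$split_seed),
  "results/preprocess_manifest.json", auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("split: %d train / %d test (stratified, seed %d)\n",
            length(prep$split$idx_train), length(prep$split$idx_test),
            prep$split$split_seed))
cat(sprintf("training class balance before SMOTE: %s\n",
            paste(names(prep$counts$train), as.integer(prep$counts$train),
                  sep = "=", collapse = ", ")))
cat(sprintf("after SMOTE: %s (%d synthetic rows)\n",
            paste(names(prep$counts$train_balanced),
                  as.integer(prep$counts$train_balanced), sep = "=",
                  collapse = ", "),
            sum(prep$smote$synthetic)))
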