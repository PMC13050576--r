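#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic high-risk antenatal cohort.
#
# Draws n patients (default 10,000, root seed 42) from the calibrated
# generative model: truncated-normal demographics, categorical ethnicity,
# score-tilted Bernoulli risk factors, score-coupled laboratory values with
# selective OGTT testing (~29.5% tested), and the threshold-triggered
# probabilistic GDM outcome (~65% positive in this enriched referral-clinic
# profile). Writes results/cohort.csv plus a JSON sidecar with the config
# echo and summary statistics.
#
# Usage: Rscript analysis/01_simulate.R [--n 10000] [--seed 42]

library(earlygdm)

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else as.integer(args[i + 1])
}
n <- get_arg("--n", 10000)
seed <- get_arg("--seed", 42)

dir.create("results", showWarnings = FALSE)
cfg <- gdm_config(n_patients = n, seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort.csv", cfg)

cat(sprintf("generated %d records (seed %d)\n", nrow(cohort), seed))
cat(sprintf("  GDM-positive: %.1f%%\n", 100 * mean(cohort$gdm)))
cat(sprintf("  age %.1f +- %.1f y; BMI %.1f; Caucasian %.1f%%\n",
            mean(cohort$age), sd(cohort$age), mean(cohort$bmi),
            100 * mean(cohort$ethnicity == "Caucasian")))
cat(sprintf("  family hx %.1f%%; prev GDM %.1f%%; PCOS %.1f%%; macrosomia %.1f%%\n",
            100 * mean(cohort$family_hx), 100 * mean(cohort$prev_gdm),
            100 * mean(cohort$pcos), 100 * mean(cohort$prev_macrosomia)))
cat(sprintf("  HbA1c %.2f +- %.2f%%; RBS %.1f; PPBS %.1f; OGTT tested %.1f%%\n",
            mean(cohort$hba1c), sd(cohort$hba1c), mean(cohort$rbs),
            mean(cohort$ppbs), 100 * mean(cohort$ogtt_tested)))
cat("wrote results/cohort.csv\n")
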