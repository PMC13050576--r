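#!/usr/bin/env Rscript
# Stage 6 — clinical tier tabulation and per-patient risk reports:
# classifies every cohort laboratory value against the published inclusive
# boundaries (RBS >=125/140, PPBS >=160/180, HbA1c >=5.7/6.0/6.5, OGTT
# >=92/180/153) and writes a tier frequency table plus JSON-lines risk
# reports for the first 100 patients.
#
# Usage: Rscript analysis/06_thresholds.R   (expects results/cohort.csv)

library(earlygdm)

cohort <- read.csv("results/cohort.csv")

tier_counts <- list()
for (analyte in names(lab_ranges())) {
  v <- cohort[[analyte]]
  v <- v[!is.na(v)]
  tiers <- classify_lab(analyte, v)
  tier_counts[[analyte]] <- as.list(table(factor(
    tiers$tier, levels = unique(c("normal", lab_tier_table()$tier)))))
}
tab <- do.call(rbind, lapply(names(tier_counts), function(a)
  data.frame(analyte = a, tier = names(tier_counts[[a]]),
             count = unlist(tier_counts[[a]]), row.names = NULL)))
tab <- tab[tab$count > 0, ]
write.csv(tab, "results/tier_counts.csv", row.names = FALSE)
cat("clinical tier frequencies:\n")
print(tab, row.names = FALSE)

con <- file("results/reports.jsonl", "w")
for (i in seq_len(min(100, nrow(cohort)))) {
  rec <- cohort[i, ]
  rep_i <- risk_report(rec, probability = rec$outcome_prob)
  writeLines(format_report_json(rep_i), con)
}
close(con)
cat("wrote results/reports.jsonl (first 100 patients)\n")
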