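# Stage 1: synthetic high-risk antenatal cohort.
#
# Generation is hierarchical: demographics -> demographic risk score ->
# risk-factor flags (prevalence-preserving logistic tilt on the demographic
# score) -> full composite score -> score-coupled laboratory values with
# selective OGTT -> threshold-triggered outcome probability -> Bernoulli
# diagnosis. Each stage draws from its own named RNG substream.

#' Composite clinical risk score
#'
#' `score = (age - 25) * 0.1 + (bmi - 23) * 0.15 + 1.5 * family_hx +
#'  2.0 * prev_gdm + 1.0 * pcos + 1.2 * prev_macrosomia +
#'  0.8 * [ethnicity is high-risk]` with all weights configurable. The score
#' may be negative (age below 25 or BMI below 23 contribute negatively).
#'
#' @param records data.frame with columns age, bmi, ethnicity, family_hx,
#'   prev_gdm, pcos, prev_macrosomia.
#' @param cfg a [gdm_config()].
#' @return numeric vector of scores.
#' @export
compute_risk_score <- function(records, cfg = gdm_config()) {
  needed <- c("age", "bmi", "ethnicity", "family_hx", "prev_gdm", "pcos",
              "prev_macrosomia")
  missing_fields <- setdiff(needed, names(records))
  if (length(missing_fields)) {
    stop("missing demographic field(s): ", paste(missing_fields, collapse = ", "))
  }
  w <- cfg$score_weights
  demographic_score(records, cfg) +
    w$family_hx * records$family_hx +
    w$prev_gdm * records$prev_gdm +
    w$pcos * records$pcos +
    w$prev_macrosomia * records$prev_macrosomia
}

# demographic-only portion of the score (age, BMI, ethnicity); used both in
# the full score and to tilt risk-factor allocation before flags exist
demographic_score <- function(records, cfg) {
  w <- cfg$score_weights
  (records$age - w$age_ref) * w$age_coeff +
    (records$bmi - w$bmi_ref) * w$bmi_coeff +
    w$high_risk_ethnicity * (records$ethnicity %in% cfg$high_risk_ethnicities)
}

#' Draw demographics for a cohort
#'
#' Age ~ Normal(28, 5) clipped to 18-45; BMI ~ Normal(24 or 26 by age
#' stratum, 4) clipped to 16-45; ethnicity ~ Categorical(config simplex);
#' booking gestational age ~ Normal(10.2, 2.3) clipped to a first-trimester
#' window. Clipping (not rejection) is used, so a small boundary mass exists.
#'
#' @param cfg a [gdm_config()].
#' @param seed RNG seed; defaults to the "demographics" substream of the
#'   config root seed.
#' @return data.frame with age, bmi, booking_ga, ethnicity.
#' @export
sample_demographics <- function(cfg = gdm_config(),
                                seed = stage_seed(cfg$seed, "demographics")) {
  validate_config(cfg)
  n <- cfg$n_patients
  if (n == 0) {
    return(data.frame(age = numeric(0), bmi = numeric(0),
                      booking_ga = numeric(0), ethnicity = character(0)))
  }
  set.seed(seed)
  age <- rnorm_clipped(n, cfg$age_mean, cfg$age_sd, cfg$age_range)
  bmi_mean <- ifelse(age < cfg$bmi_age_cut, cfg$bmi_mean_young, cfg$bmi_mean_old)
  bmi <- clip(stats::rnorm(n, bmi_mean, cfg$bmi_sd), cfg$bmi_range[1], cfg$bmi_range[2])
  booking_ga <- rnorm_clipped(n, cfg$booking_ga_mean, cfg$booking_ga_sd,
                              cfg$booking_ga_range)
  ethnicity <- sample(names(cfg$ethnicity_probs), n, replace = TRUE,
                      prob = cfg$ethnicity_probs)
  data.frame(age = age, bmi = bmi, booking_ga = booking_ga,
             ethnicity = ethnicity, stringsAsFactors = FALSE)
}

#' Allocate binary clinical risk factors
#'
#' Each flag is Bernoulli with an individual probability
#' `plogis(a + tilt * demographic_score)`; the intercept `a` is solved
#' numerically per cohort so the mean probability equals the configured
#' marginal prevalence. The tilt is monotone increasing in the score; a tilt
#' of zero reduces to independent draws at the marginal prevalence.
#'
#' @param demographics data.frame from [sample_demographics()].
#' @param cfg a [gdm_config()].
#' @param seed RNG seed (default: "risk_factors" substream).
#' @return `demographics` with columns family_hx, prev_gdm, pcos,
#'   prev_macrosomia appended (0/1 integers).
#' @export
assign_risk_factors <- function(demographics, cfg = gdm_config(),
                                seed = stage_seed(cfg$seed, "risk_factors")) {
  n <- nrow(demographics)
  s <- demographic_score(demographics, cfg)
  set.seed(seed)
  for (flag in names(cfg$prevalence)) {
    target <- cfg$prevalence[[flag]]
    p <- tilted_probs(s, cfg$flag_tilt, target)
    demographics[[flag]] <- as.integer(stats::runif(n) < p)
  }
  demographics
}

# per-individual Bernoulli probabilities plogis(a + tilt * s) with the
# intercept a chosen so mean(p) == target
tilted_probs <- function(s, tilt, target) {
  if (tilt == 0 || stats::sd(s) == 0) return(rep(target, length(s)))
  f <- function(a) mean(stats::plogis(a + tilt * s)) - target
  a <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  stats::plogis(a + tilt * s)
}

#' Draw laboratory values with selective OGTT testing
#'
#' Each analyte is Normal(base_mean + shift * score, base_sd), clipped to
#' its reference range. The OGTT triple is drawn only for the tested subset:
#' the top `ogtt_tested_fraction` of the cohort ranked by score plus Gumbel
#' noise (emulating selective testing of higher-risk patients); everyone
#' else carries NA in all three OGTT columns.
#'
#' @param records data.frame containing `risk_score`.
#' @param cfg a [gdm_config()].
#' @param seed RNG seed (default: "labs" substream).
#' @return `records` with rbs, ppbs, hba1c, ogtt_fasting, ogtt_1h, ogtt_2h
#'   and logical `ogtt_tested` appended.
#' @export
sample_lab_values <- function(records, cfg = gdm_config(),
                              seed = stage_seed(cfg$seed, "labs")) {
  validate_config(cfg)
  if (is.null(records$risk_score)) stop("risk_score must be computed first")
  n <- nrow(records)
  rngs <- lab_ranges()
  set.seed(seed)
  for (lab in c("rbs", "ppbs", "hba1c")) {
    m <- cfg$lab_models[[lab]]
    records[[lab]] <- rnorm_clipped(n, m$base_mean + m$shift * records$risk_score,
                                    m$base_sd, rngs[[lab]])
  }
  k <- round(n * cfg$ogtt_tested_fraction)
  sel <- records$risk_score + rgumbel(n, cfg$ogtt_selection_noise)
  tested <- rank(-sel, ties.method = "first") <= k
  for (lab in OGTT_COLS) {
    m <- cfg$lab_models[[lab]]
    v <- rep(NA_real_, n)
    v[tested] <- rnorm_clipped(sum(tested),
                               m$base_mean + m$shift * records$risk_score[tested],
                               m$base_sd, rngs[[lab]])
    records[[lab]] <- v
  }
  records$ogtt_tested <- tested
  records
}

#' Threshold-triggered outcome probability
#'
#' `p = clip(base + coeff * score + increments, 0, cap)` where the
#' increments come from the shared clinical tier table: within one analyte
#' only the single highest crossed tier applies (RBS >=140: +0.40 else
#' >=125: +0.20; PPBS >=180: +0.30 else >=160: +0.15; HbA1c >=6.5: +0.50
#' else >=6.0: +0.25 else >=5.7: +0.10), and meeting any OGTT diagnostic
#' criterion (fasting >=92, 1-h >=180, 2-h >=153) adds +0.40. Missing OGTT
#' contributes nothing. Deterministic given the record.
#'
#' @param records data.frame with risk_score and lab columns (OGTT possibly NA).
#' @param cfg a [gdm_config()].
#' @return numeric vector of probabilities in `[0, prob_cap]`.
#' @export
compute_outcome_probability <- function(records, cfg = gdm_config()) {
  rngs <- lab_ranges()
  tiers <- lab_tier_table()
  n <- nrow(records)
  inc <- numeric(n)
  for (lab in c("rbs", "ppbs", "hba1c")) {
    v <- records[[lab]]
    if (any(v < rngs[[lab]][1] | v > rngs[[lab]][2], na.rm = TRUE)) {
      stop("lab '", lab, "' outside declared range [", rngs[[lab]][1], ", ",
           rngs[[lab]][2], "]; generation should have clipped")
    }
    rows <- tiers[tiers$analyte == lab, ]
    rows <- rows[order(-rows$level), ]          # highest tier first
    add <- numeric(n)
    remaining <- rep(TRUE, n)
    for (i in seq_len(nrow(rows))) {
      hit <- remaining & !is.na(v) & v >= rows$threshold[i]
      add[hit] <- rows$increment[i]
      remaining <- remaining & !hit              # non-cumulative within analyte
    }
    inc <- inc + add
  }
  crit <- lab_tier_table()
  ogtt_rows <- crit[crit$analyte %in% OGTT_COLS, ]
  any_ogtt <- rep(FALSE, n)
  for (i in seq_len(nrow(ogtt_rows))) {
    v <- records[[ogtt_rows$analyte[i]]]
    if (any(v < rngs[[ogtt_rows$analyte[i]]][1] |
            v > rngs[[ogtt_rows$analyte[i]]][2], na.rm = TRUE)) {
      stop("lab '", ogtt_rows$analyte[i], "' outside declared range")
    }
    any_ogtt <- any_ogtt | (!is.na(v) & v >= ogtt_rows$threshold[i])
  }
  inc <- inc + OGTT_INCREMENT * any_ogtt
  inc <- inc * (cfg$increment_scale %||% 1)
  clip(cfg$base_outcome_prob + cfg$score_to_prob_coeff * records$risk_score + inc,
       0, cfg$prob_cap)
}

#' Generate a full synthetic cohort
#'
#' Runs the generation stages in order (demographics, flags, composite
#' score, labs with selective OGTT, outcome probability, Bernoulli
#' diagnosis) under named substreams of the root seed, so identical configs
#' yield identical cohorts.
#'
#' @param cfg a [gdm_config()].
#' @return data.frame with one row per patient: demographics, risk-factor
#'   flags, labs (OGTT NA when untested), `risk_score`, `outcome_prob`,
#'   and binary `gdm`.
#' @examples
#' cohort <- generate_cohort(gdm_config(n_patients = 200, seed = 7))
#' mean(cohort$gdm)
#' @export
generate_cohort <- function(cfg = gdm_config()) {
  validate_config(cfg)
  records <- sample_demographics(cfg)
  if (nrow(records) == 0) return(records)
  records <- assign_risk_factors(records, cfg)
  records$risk_score <- compute_risk_score(records, cfg)
  records <- sample_lab_values(records, cfg)
  records$outcome_prob <- compute_outcome_probability(records, cfg)
  set.seed(stage_seed(cfg$seed, "outcome"))
  records$gdm <- stats::rbinom(nrow(records), 1, records$outcome_prob)
  records
}

#' Write a cohort to CSV with a JSON summary sidecar
#'
#' Missing OGTT values are written as empty fields. The sidecar echoes the
#' configuration and records marginal summary statistics.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path output CSV path.
#' @param cfg the generating config (echoed into the sidecar).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, cfg = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  summary <- list(
    n = nrow(cohort),
    gdm_positive_fraction = mean(cohort$gdm),
    ogtt_tested_fraction = mean(cohort$ogtt_tested),
    means = lapply(cohort[sapply(cohort, is.numeric)],
                   function(x) mean(x, na.rm = TRUE))
  )
  sidecar <- list(config = unclass(cfg), summary = summary)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
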