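#' Generator configuration for the synthetic antenatal cohort
#'
#' Returns the full set of generation parameters with their defaults: the
#' published demographic distributions, risk-factor prevalences, composite
#' risk-score weights, tier-triggered outcome increments, and the calibration
#' constants (lab base distributions, score-coupling shifts, score-to-
#' probability coefficient) that the source tables leave free. Calibration
#' constants were solved once so that, at n = 10,000, cohort marginals
#' reproduce the reported descriptive statistics (RBS 109.1 +- 18.8, PPBS
#' 142.5 +- 24.2, HbA1c 5.72 +- 0.58, tested-subset OGTT 98.5/181.4/156.3,
#' overall positive fraction ~0.65).
#'
#' @param n_patients cohort size (default 10,000).
#' @param seed root seed; every stage draws from a named substream derived
#'   from it via [stage_seed()].
#' @param ... named overrides for any default listed below.
#' @return object of class `gdm_config` (a validated named list).
#' @examples
#' cfg <- gdm_config(n_patients = 500, seed = 1)
#' cfg$prevalence[["family_hx"]]
#' @export
gdm_config <- function(n_patients = 10000, seed = 42, ...) {
  cfg <- list(
    n_patients = n_patients,
    seed = seed,

    # demographics
    age_mean = 28, age_sd = 5, age_range = c(18, 45),
    bmi_mean_young = 24, bmi_mean_old = 26, bmi_age_cut = 30,
    bmi_sd = 4, bmi_range = c(16, 45),
    booking_ga_mean = 10.2, booking_ga_sd = 2.3, booking_ga_range = c(6, 14),
    ethnicity_probs = c(Caucasian = 0.40, Asian = 0.25, Hispanic = 0.15,
                        African = 0.12, Other = 0.08),

    # clinical risk factors: marginal prevalences and the logistic tilt that
    # couples them to the demographic risk score (intercept re-solved per
    # cohort so the marginal is preserved)
    prevalence = c(family_hx = 0.25, prev_gdm = 0.12, pcos = 0.15,
                   prev_macrosomia = 0.10),
    flag_tilt = 0.3,

    # composite risk score weights
    score_weights = list(
      age_coeff = 0.1, age_ref = 25,
      bmi_coeff = 0.15, bmi_ref = 23,
      family_hx = 1.5, prev_gdm = 2.0, pcos = 1.0, prev_macrosomia = 1.2,
      high_risk_ethnicity = 0.8
    ),
    high_risk_ethnicities = c("Asian", "Hispanic"),

    # laboratory models: value ~ Normal(base_mean + shift * score, base_sd),
    # clipped to lab_ranges(). base_mean/base_sd are calibration constants
    # (see scratch note above); shift is the score coupling per score unit.
    lab_models = list(
      rbs          = list(base_mean = 103.580, base_sd = 18.609, shift = 3.0),
      ppbs         = list(base_mean = 137.193, base_sd = 24.141, shift = 3.0),
      hba1c        = list(base_mean = 5.456,   base_sd = 0.532,  shift = 0.15),
      ogtt_fasting = list(base_mean = 92.020,  base_sd = 11.220, shift = 2.0),
      ogtt_1h      = list(base_mean = 165.270, base_sd = 31.660, shift = 5.0),
      ogtt_2h      = list(base_mean = 143.259, base_sd = 25.675, shift = 4.0)
    ),

    # selective OGTT: the top `ogtt_tested_fraction` of (score + Gumbel
    # noise) are tested; everyone else has all three values missing
    ogtt_tested_fraction = 0.295,
    ogtt_selection_noise = 1.0,

    # outcome model
    base_outcome_prob = 0.10,
    score_to_prob_coeff = 0.254,  # calibrated so mean outcome prob ~= 0.65
    increment_scale = 1,          # multiplies every tier increment (0 = off)
    prob_cap = 0.95
  )

  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "gdm_config")
}

#' Validate a generator configuration
#'
#' @param cfg a `gdm_config`.
#' @return `cfg`, invisibly, or an error describing the violated invariant.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "gdm_config"))
  if (!(is.numeric(cfg$n_patients) && length(cfg$n_patients) == 1L &&
        cfg$n_patients >= 0 && cfg$n_patients == floor(cfg$n_patients))) {
    stop("n_patients must be a non-negative integer")
  }
  if (abs(sum(cfg$ethnicity_probs) - 1) > 1e-9 || any(cfg$ethnicity_probs < 0)) {
    stop("ethnicity_probs must be a probability simplex (sum 1, all >= 0)")
  }
  probs <- c(cfg$prevalence, cfg$base_outcome_prob, cfg$prob_cap,
             cfg$ogtt_tested_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all prevalences and probabilities must lie in [0, 1]")
  }
  for (rng in list(cfg$age_range, cfg$bmi_range, cfg$booking_ga_range)) {
    if (rng[1] >= rng[2]) stop("all ranges must have low < high")
  }
  for (nm in names(cfg$lab_models)) {
    if (cfg$lab_models[[nm]]$base_sd < 0) {
      stop("negative base_sd for lab '", nm, "'")
    }
  }
  invisible(cfg)
}
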