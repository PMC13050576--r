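# Cohort simulator: score arithmetic, distributional marginals,
# determinism, range conservation, and the threshold-triggered outcome
# model.

test_that("composite risk score matches hand-evaluated weights", {
  cfg <- gdm_config()
  ref <- make_record()  # age 25, BMI 23, no flags, Caucasian
  expect_identical(compute_risk_score(ref, cfg), 0)

  r1 <- make_record(age = 35, bmi = 30, family_hx = 1)
  expect_equal(compute_risk_score(r1, cfg), 3.55)  # 1.0 + 1.05 + 1.5

  r2 <- make_record(age = 30, bmi = 27, prev_gdm = 1, pcos = 1,
                    ethnicity = "Asian")
  expect_equal(compute_risk_score(r2, cfg), 4.9)   # 0.5 + 0.6 + 2 + 1 + 0.8

  # scores can be negative below the reference offsets
  expect_lt(compute_risk_score(make_record(age = 19, bmi = 17), cfg), 0)

  bad <- make_record()
  bad$bmi <- NULL
  expect_error(compute_risk_score(bad, cfg), "bmi")
})

test_that("cohort generation is seed-deterministic and range-conserving", {
  cfg <- gdm_config(n_patients = 800, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(gdm_config(n_patients = 800, seed = 100))))

  expect_true(all(a$age >= 18 & a$age <= 45))
  expect_true(all(a$bmi >= 16 & a$bmi <= 45))
  rngs <- lab_ranges()
  for (lab in c("rbs", "ppbs", "hba1c")) {
    expect_true(all(a[[lab]] >= rngs[[lab]][1] & a[[lab]] <= rngs[[lab]][2]))
  }
  # OGTT is all-three-present or all-three-missing per record
  n_missing <- rowSums(is.na(a[, c("ogtt_fasting", "ogtt_1h", "ogtt_2h")]))
  expect_true(all(n_missing %in% c(0, 3)))
  expect_identical(n_missing == 0, a$ogtt_tested)
  expect_equal(mean(a$ogtt_tested), round(800 * 0.295) / 800)

  # outcome probabilities respect the cap
  expect_true(all(a$outcome_prob >= 0 & a$outcome_prob <= 0.95))
})

test_that("changing downstream stage parameters never perturbs upstream draws", {
  base <- gdm_config(n_patients = 300, seed = 5)
  alt <- gdm_config(n_patients = 300, seed = 5, score_to_prob_coeff = 0)
  expect_identical(sample_demographics(base), sample_demographics(alt))
  a <- generate_cohort(base)
  b <- generate_cohort(alt)
  expect_identical(a[, c("age", "bmi", "ethnicity", "family_hx", "rbs")],
                   b[, c("age", "bmi", "ethnicity", "family_hx", "rbs")])
})

test_that("demographic and flag marginals recover configured values at n = 10,000", {
  cfg <- gdm_config(n_patients = 10000, seed = 314)
  ch <- generate_cohort(cfg)
  n <- nrow(ch)
  se_p <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(ch$age) - 28), 3 * 5 / sqrt(n))
  expect_lt(abs(sd(ch$age) - 4.9), 0.15)   # clipping shrinks the SD below 5
  expect_lt(abs(mean(ch$ethnicity == "Caucasian") - 0.40), 3 * se_p(0.40))
  for (flag in names(cfg$prevalence)) {
    expect_lt(abs(mean(ch[[flag]]) - cfg$prevalence[[flag]]),
              3 * se_p(cfg$prevalence[[flag]]))
  }
  # lab calibration: HbA1c marginal reproduces the target mean/SD
  expect_lt(abs(mean(ch$hba1c) - 5.72), 3 * 0.58 / sqrt(n))
  expect_lt(abs(sd(ch$hba1c) - 0.58), 0.03)
})

test_that("risk-factor tilt is monotone, prevalence-preserving, and degenerates cleanly", {
  cfg <- gdm_config(n_patients = 20000, seed = 77)
  demo <- sample_demographics(cfg)
  flags <- assign_risk_factors(demo, cfg)
  s <- (demo$age - 25) * 0.1 + (demo$bmi - 23) * 0.15 +
    0.8 * (demo$ethnicity %in% c("Asian", "Hispanic"))
  hi <- s > median(s)
  for (flag in names(cfg$prevalence)) {
    expect_gt(mean(flags[[flag]][hi]), mean(flags[[flag]][!hi]))
  }
  # zero tilt: flags independent of score, marginal exact in expectation
  cfg0 <- gdm_config(n_patients = 20000, seed = 77, flag_tilt = 0)
  flags0 <- assign_risk_factors(demo, cfg0)
  expect_lt(abs(mean(flags0$family_hx) - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
  expect_lt(abs(cor(flags0$family_hx, s)), 3 / sqrt(20000))
})

test_that("labs couple to the risk score and decouple when shifts are zero", {
  cfg <- gdm_config(n_patients = 5000, seed = 11)
  ch <- generate_cohort(cfg)
  expect_gt(cor(ch$risk_score, ch$hba1c), 3 / sqrt(nrow(ch)))

  cfg0 <- gdm_config(n_patients = 5000, seed = 11)
  for (lab in names(cfg0$lab_models)) cfg0$lab_models[[lab]]$shift <- 0
  ch0 <- generate_cohort(cfg0)
  expect_lt(abs(cor(ch0$risk_score, ch0$hba1c)), 3 / sqrt(nrow(ch0)))
})

test_that("outcome probability follows the additive tier model", {
  cfg <- gdm_config()
  # all labs below every threshold, zero score: base rate only
  r <- make_record(rbs = 100, ppbs = 120, hba1c = 5.0)
  expect_equal(compute_outcome_probability(r, cfg), 0.10)

  # diagnostic HbA1c alone: highest tier only, non-cumulative
  r <- make_record(hba1c = 6.6)
  expect_equal(compute_outcome_probability(r, cfg), 0.60)  # 0.10 + 0.50

  # worked example with explicit coefficient 0.05: 0.10 + 0.245 + 0.40
  cfg05 <- gdm_config(score_to_prob_coeff = 0.05)
  r <- make_record(age = 30, bmi = 27, prev_gdm = 1, pcos = 1,
                   ethnicity = "Asian", rbs = 145)
  expect_equal(compute_outcome_probability(r, cfg05), 0.745)

  # missing OGTT contributes nothing; meeting any criterion adds 0.40
  r_no <- make_record()
  r_ogtt <- make_record(ogtt_fasting = 95, ogtt_1h = 150, ogtt_2h = 120)
  expect_equal(compute_outcome_probability(r_ogtt, cfg) -
                 compute_outcome_probability(r_no, cfg), 0.40)
  # sub-threshold OGTT adds nothing
  r_low <- make_record(ogtt_fasting = 85, ogtt_1h = 150, ogtt_2h = 120)
  expect_equal(compute_outcome_probability(r_low, cfg),
               compute_outcome_probability(r_no, cfg))

  # out-of-range lab is rejected
  r_bad <- make_record(rbs = 300)
  expect_error(compute_outcome_probability(r_bad, cfg), "range")
})

test_that("outcome probability is monotone in flags and lab threshold crossings", {
  cfg <- gdm_config()
  base_rec <- make_record(age = 30, bmi = 26, rbs = 120, ppbs = 155, hba1c = 5.6)
  p0 <- compute_outcome_probability(base_rec, cfg)
  for (flag in c("family_hx", "prev_gdm", "pcos", "prev_macrosomia")) {
    r <- base_rec
    r[[flag]] <- 1
    r$risk_score <- compute_risk_score(r, cfg)
    expect_gte(compute_outcome_probability(r, cfg), p0)
  }
  grids <- list(rbs = seq(70, 200, by = 2.5), ppbs = seq(90, 250, by = 2.5),
                hba1c = seq(4, 8, by = 0.05))
  for (lab in names(grids)) {
    r <- base_rec[rep(1, length(grids[[lab]])), ]
    r[[lab]] <- grids[[lab]]
    p <- compute_outcome_probability(r, cfg)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("probability bounds hold on a grid of extreme inputs", {
  cfg <- gdm_config()
  grid <- expand.grid(age = c(18, 45), bmi = c(16, 45),
                      ethnicity = c("African", "Asian"),
                      family_hx = c(0, 1), prev_gdm = c(0, 1),
                      hba1c = c(4, 8), rbs = c(70, 200), ppbs = c(90, 250),
                      stringsAsFactors = FALSE)
  rec <- make_record()[rep(1, nrow(grid)), ]
  for (col in names(grid)) rec[[col]] <- grid[[col]]
  rec$ogtt_fasting <- 140; rec$ogtt_1h <- 250; rec$ogtt_2h <- 220
  rec$risk_score <- compute_risk_score(rec, cfg)
  p <- compute_outcome_probability(rec, cfg)
  expect_true(all(p >= 0 & p <= cfg$prob_cap))
  expect_true(any(p == cfg$prob_cap))  # the cap binds at the extremes
})

test_that("base-rate-only limit: no increments, no score coupling", {
  cfg <- gdm_config(n_patients = 10000, seed = 3, score_to_prob_coeff = 0,
                    increment_scale = 0)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$outcome_prob == 0.10))
  expect_lt(abs(mean(ch$gdm) - 0.10), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("empty and invalid configs are handled", {
  expect_identical(nrow(generate_cohort(gdm_config(n_patients = 0))), 0L)
  bad <- gdm_config()
  bad$ethnicity_probs <- c(Caucasian = 0.5, Asian = 0.5, Hispanic = 0.5,
                           African = 0, Other = 0)
  expect_error(validate_config(bad), "simplex")
  bad2 <- gdm_config()
  bad2$lab_models$rbs$base_sd <- -1
  expect_error(validate_config(bad2), "base_sd")
  expect_error(gdm_config(not_a_field = 1), "unknown config field")
})

test_that("cohort CSV round-trips byte-identically under one seed", {
  cfg <- gdm_config(n_patients = 150, seed = 8)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg), f1, cfg)
  write_cohort(generate_cohort(cfg), f2, cfg)
  expect_identical(readLines(f1), readLines(f2))
  back <- read.csv(f1)
  expect_identical(nrow(back), 150L)
  expect_true(anyNA(back$ogtt_fasting))  # empty fields read back as NA
})
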