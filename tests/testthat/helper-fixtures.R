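# Shared fixtures, built in code at test time.

# a single fully-specified patient record (data.frame row) with labs
make_record <- function(age = 25, bmi = 23, ethnicity = "Caucasian",
                        family_hx = 0, prev_gdm = 0, pcos = 0,
                        prev_macrosomia = 0, rbs = 100, ppbs = 120,
                        hba1c = 5.0, ogtt_fasting = NA_real_,
                        ogtt_1h = NA_real_, ogtt_2h = NA_real_,
                        booking_ga = 10, risk_score = NULL) {
  rec <- data.frame(age = age, bmi = bmi, booking_ga = booking_ga,
                    ethnicity = ethnicity, family_hx = family_hx,
                    prev_gdm = prev_gdm, pcos = pcos,
                    prev_macrosomia = prev_macrosomia,
                    rbs = rbs, ppbs = ppbs, hba1c = hba1c,
                    ogtt_fasting = ogtt_fasting, ogtt_1h = ogtt_1h,
                    ogtt_2h = ogtt_2h, stringsAsFactors = FALSE)
  rec$risk_score <- risk_score %||% compute_risk_score(rec, gdm_config())
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small labelled two-class dataset with a linear signal, for model tests
make_toy_classification <- function(n = 200, p = 4, seed = 1, sep = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.integer(sep * x[, 1] + rnorm(n) > 0)
  list(x = as.data.frame(x), y = y)
}
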