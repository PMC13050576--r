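# Deterministic clinical tiering of first-trimester laboratory values.
# Boundary constants live in lab_tier_table() (shared with the simulator's
# outcome model) and are uniformly inclusive (>=).

#' Classify a laboratory value into its clinical tier
#'
#' Returns the highest tier whose boundary the value meets; values below
#' every boundary are "normal". Boundaries are inclusive. Vectorized over
#' `value`.
#'
#' @param analyte one of rbs, ppbs, hba1c, ogtt_fasting, ogtt_1h, ogtt_2h.
#' @param value numeric value(s) within the analyte's reference range.
#' @return data.frame with columns analyte, value, tier, level (0 = normal,
#'   higher = worse), boundary (threshold crossed, NA for normal).
#' @examples
#' classify_lab("hba1c", c(5.5, 5.8, 6.2, 6.5))
#' @export
classify_lab <- function(analyte, value) {
  rngs <- lab_ranges()
  if (!analyte %in% names(rngs)) stop("unknown analyte: ", analyte)
  rng <- rngs[[analyte]]
  if (any(is.na(value)) || any(value < rng[1] | value > rng[2])) {
    stop("value out of range [", rng[1], ", ", rng[2], "] for ", analyte)
  }
  rows <- lab_tier_table()
  rows <- rows[rows$analyte == analyte, ]
  rows <- rows[order(rows$level), ]
  tier <- rep("normal", length(value))
  level <- rep(0L, length(value))
  boundary <- rep(NA_real_, length(value))
  for (i in seq_len(nrow(rows))) {
    hit <- value >= rows$threshold[i]
    tier[hit] <- rows$tier[i]
    level[hit] <- rows$level[i]
    boundary[hit] <- rows$threshold[i]
  }
  data.frame(analyte = analyte, value = value, tier = tier, level = level,
             boundary = boundary, stringsAsFactors = FALSE)
}

#' Structured per-patient risk report
#'
#' Aggregates demographics, risk flags, per-analyte clinical tiers, the
#' model's predicted probability, and (optionally) the top attribution
#' ledger into one serializable structure. Deterministic given its inputs.
#'
#' @param record one-row data.frame (a cohort record; OGTT may be NA).
#' @param probability model-predicted GDM probability in `[0, 1]`.
#' @param attributions optional `gdm_attributions` row for this patient
#'   (list with `waterfall`-style steps), attached verbatim.
#' @param n_top number of attribution steps to keep (default 5).
#' @return list of class `gdm_risk_report`.
#' @export
risk_report <- function(record, probability, attributions = NULL, n_top = 5) {
  stopifnot(nrow(record) == 1, probability >= 0, probability <= 1)
  tiers <- list()
  for (analyte in names(lab_ranges())) {
    v <- record[[analyte]]
    if (!is.null(v) && !is.na(v)) {
      tiers[[analyte]] <- classify_lab(analyte, v)
    }
  }
  flagged <- Filter(function(t) t$level > 0, tiers)
  report <- list(
    demographics = list(age = record$age, bmi = record$bmi,
                        booking_ga = record$booking_ga,
                        ethnicity = record$ethnicity %||% NA),
    risk_factors = list(family_hx = record$family_hx,
                        prev_gdm = record$prev_gdm, pcos = record$pcos,
                        prev_macrosomia = record$prev_macrosomia),
    lab_tiers = lapply(tiers, function(t) list(value = t$value, tier = t$tier,
                                               boundary = t$boundary)),
    flagged_tiers = names(flagged),
    model_probability = probability
  )
  if (!is.null(attributions)) {
    wf <- waterfall(attributions, 1)
    report$top_attributions <- utils::head(wf$steps, n_top)
    report$attribution_base <- wf$base_value
  }
  class(report) <- "gdm_risk_report"
  report
}

#' Serialize a risk report to JSON
#'
#' @param report a `gdm_risk_report`.
#' @return a JSON string (stable for identical inputs).
#' @export
format_report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA, na = "null")
}
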