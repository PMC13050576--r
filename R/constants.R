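# Single source of truth for laboratory reference ranges, clinical tier
# boundaries, and the outcome-probability increment attached to each tier.
# Both the cohort simulator and the clinical tiering functions read from
# these tables, so a boundary can never drift between the two.

#' Laboratory reference ranges (first-trimester panel)
#'
#' Generated values are clipped to these ranges and out-of-range inputs to
#' downstream classifiers are rejected.
#'
#' @return named list of `c(low, high)` ranges, one per analyte.
#' @export
lab_ranges <- function() {
  list(
    rbs          = c(70, 200),   # random blood sugar, mg/dL
    ppbs         = c(90, 250),   # 2-h post-prandial blood sugar, mg/dL
    hba1c        = c(4.0, 8.0),  # glycated hemoglobin, %
    ogtt_fasting = c(70, 140),   # mg/dL
    ogtt_1h      = c(100, 250),  # mg/dL
    ogtt_2h      = c(90, 220)    # mg/dL
  )
}

#' Clinical tier boundaries and outcome-probability increments
#'
#' One row per (analyte, boundary). Boundaries are inclusive (`>=`).
#' `level` orders tiers within an analyte (0 = normal, higher = worse);
#' `increment` is the absolute probability added to the outcome model when
#' the value is in that tier and no higher tier applies (within one analyte
#' only the single highest crossed tier counts). The OGTT criteria share one
#' pooled +0.40 increment applied when any of the three is met, so their
#' per-row increment is recorded as NA here.
#'
#' @return data.frame with columns analyte, tier, level, threshold, increment.
#' @export
lab_tier_table <- function() {
  data.frame(
    analyte = c("rbs", "rbs",
                "ppbs", "ppbs",
                "hba1c", "hba1c", "hba1c",
                "ogtt_fasting", "ogtt_1h", "ogtt_2h"),
    tier = c("borderline", "concerning",
             "borderline", "concerning",
             "intermediate", "high", "diagnostic",
             "diagnostic", "diagnostic", "diagnostic"),
    level = c(1L, 2L, 1L, 2L, 1L, 2L, 3L, 3L, 3L, 3L),
    threshold = c(125, 140, 160, 180, 5.7, 6.0, 6.5, 92, 180, 153),
    increment = c(0.20, 0.40, 0.15, 0.30, 0.10, 0.25, 0.50, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# pooled increment when any OGTT diagnostic criterion is met
OGTT_INCREMENT <- 0.40

# the five ethnicity categories, in fixed order (reference category first
# in the sense of one-hot drop-first encoding: African encodes as all-zeros)
ETHNICITIES <- c("African", "Asian", "Caucasian", "Hispanic", "Other")

# columns that may legitimately be missing (test not performed)
OGTT_COLS <- c("ogtt_fasting", "ogtt_1h", "ogtt_2h")
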