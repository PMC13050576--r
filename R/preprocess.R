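# Stage 2: raw cohort -> model-ready matrices.
# Fixed order: encode ethnicity -> zero-impute OGTT -> stratified 80/20
# split (seed 42) -> standardize continuous features (train-fitted) ->
# SMOTE-balance the training partition only.

# continuous features subject to standardization; binary flags and one-hot
# ethnicity indicators keep their interpretable 0/1 states
CONTINUOUS_FEATURES <- c("age", "bmi", "booking_ga", "rbs", "ppbs", "hba1c",
                         "ogtt_fasting", "ogtt_1h", "ogtt_2h")

#' One-hot encode ethnicity with the drop-first strategy
#'
#' Adds `ethnicity_Asian`, `ethnicity_Caucasian`, `ethnicity_Hispanic`,
#' `ethnicity_Other`; the reference category (African) is implicitly the
#' all-zeros pattern. The original column is dropped.
#'
#' @param cohort data.frame with an `ethnicity` column.
#' @return the data.frame with four 0/1 indicator columns in its place.
#' @export
encode_ethnicity <- function(cohort) {
  bad <- setdiff(unique(cohort$ethnicity), ETHNICITIES)
  if (length(bad)) {
    stop("unknown ethnicity value(s): ", paste(bad, collapse = ", "))
  }
  for (eth in setdiff(ETHNICITIES, "African")) {
    cohort[[paste0("ethnicity_", eth)]] <- as.integer(cohort$ethnicity == eth)
  }
  cohort$ethnicity <- NULL
  cohort
}

#' Zero-impute missing OGTT values
#'
#' Replaces NA in the three OGTT columns with 0, deliberately creating a
#' three-state encoding: elevated (high risk), normal (low risk), and zero
#' (test not performed -- itself an informative signal of low pre-test
#' probability). NA anywhere else is an error.
#'
#' @param df data.frame; NA allowed only in OGTT columns.
#' @return the data.frame with no missing cells; attribute `n_imputed`
#'   records how many cells were filled.
#' @export
impute_ogtt_zero <- function(df) {
  other <- setdiff(names(df), OGTT_COLS)
  bad <- other[vapply(df[other], anyNA, logical(1))]
  if (length(bad)) {
    stop("missing values outside OGTT columns: ", paste(bad, collapse = ", "))
  }
  n_imputed <- 0L
  for (col in intersect(OGTT_COLS, names(df))) {
    idx <- is.na(df[[col]])
    n_imputed <- n_imputed + sum(idx)
    df[[col]][idx] <- 0
  }
  attr(df, "n_imputed") <- n_imputed
  df
}

#' Stratified train/test split
#'
#' Per-class allocation proportional to `train_fraction` with
#' largest-remainder rounding (ties broken by class label order), so class
#' proportions in each partition stay within one record of the full-data
#' proportion. Seeded and deterministic.
#'
#' @param x data.frame or matrix of features.
#' @param y binary label vector aligned to rows of `x`.
#' @param train_fraction proportion of rows assigned to training (default 0.8).
#' @param seed RNG seed (default 42).
#' @return list with `train_x`, `train_y`, `test_x`, `test_y`,
#'   `idx_train`, `idx_test`, `split_seed`, `train_fraction`.
#' @export
stratified_split <- function(x, y, train_fraction = 0.8, seed = 42) {
  stopifnot(train_fraction > 0, train_fraction < 1, nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("both classes must be present")
  counts <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  if (any(counts < 2)) {
    stop("class ", classes[which.min(counts)], " has fewer than 2 records")
  }
  target_total <- round(train_fraction * length(y))
  base <- floor(train_fraction * counts)
  rem <- train_fraction * counts - base
  extra <- target_total - sum(base)
  take <- base
  if (extra > 0) {
    # largest remainder; ties resolved by class label order
    ord <- order(-rem, seq_along(classes))
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  }
  set.seed(seed)
  idx_train <- integer(0)
  for (i in seq_along(classes)) {
    members <- which(y == classes[i])
    idx_train <- c(idx_train, sample(members, take[i]))
  }
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(y), idx_train)
  list(train_x = x[idx_train, , drop = FALSE], train_y = y[idx_train],
       test_x = x[idx_test, , drop = FALSE], test_y = y[idx_test],
       idx_train = idx_train, idx_test = idx_test,
       split_seed = seed, train_fraction = train_fraction)
}

#' Standardize continuous features, fitted on training data only
#'
#' z = (x - train_mean) / train_sd for the listed features, applied to both
#' partitions; all other columns are untouched. Parameters are returned for
#' audit, and depend only on the training rows (leakage guard).
#'
#' @param train_x,test_x data.frames with identical columns.
#' @param features character vector of columns to scale
#'   (default: the continuous feature list).
#' @return list with scaled `train`, `test`, and a `params` data.frame
#'   (feature, mean, sd).
#' @export
standardize <- function(train_x, test_x, features = CONTINUOUS_FEATURES) {
  features <- intersect(features, names(train_x))
  mu <- vapply(train_x[features], mean, numeric(1))
  sdev <- vapply(train_x[features], stats::sd, numeric(1))
  if (any(sdev == 0)) {
    stop("constant feature(s) cannot be standardized: ",
         paste(features[sdev == 0], collapse = ", "))
  }
  for (f in features) {
    train_x[[f]] <- (train_x[[f]] - mu[[f]]) / sdev[[f]]
    test_x[[f]] <- (test_x[[f]] - mu[[f]]) / sdev[[f]]
  }
  list(train = train_x, test = test_x,
       params = data.frame(feature = features, mean = unname(mu),
                           sd = unname(sdev), stringsAsFactors = FALSE))
}

#' SMOTE: balance classes by minority interpolation
#'
#' Synthetic minority rows are `x + u * (x_nn - x)` with `u ~ Uniform(0,1)`
#' and `x_nn` one of the `k` nearest minority neighbours (Euclidean, in the
#' supplied -- post-scaling -- feature space). Original rows are preserved
#' verbatim; output classes have exactly equal counts. Intended for the
#' training partition only.
#'
#' @param x data.frame or matrix of features (fully numeric).
#' @param y binary label vector.
#' @param k_neighbors number of nearest neighbours (default 5).
#' @param seed RNG seed.
#' @return list with balanced `x`, `y`, logical `synthetic` flag per row,
#'   and `parents` (2-column matrix of minority row indices, NA for
#'   original rows).
#' @export
smote_balance <- function(x, y, k_neighbors = 5, seed = 42) {
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2)
  n_by <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  minority <- classes[which.min(n_by)]
  n_syn <- abs(diff(n_by))
  xm <- as.matrix(x)
  if (n_syn == 0) {
    return(list(x = x, y = y, synthetic = rep(FALSE, length(y)),
                parents = matrix(NA_integer_, length(y), 2)))
  }
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  if (n_min <= k_neighbors) {
    stop("minority count (", n_min, ") must exceed k_neighbors (",
         k_neighbors, "); use a smaller k")
  }
  xmin <- xm[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xmin))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d[i, ])[seq_len(k_neighbors)]))
  set.seed(seed)
  base_rows <- sample.int(n_min, n_syn, replace = TRUE)
  nbr_pick <- nn[cbind(base_rows, sample.int(k_neighbors, n_syn, replace = TRUE))]
  u <- stats::runif(n_syn)
  synth <- xmin[base_rows, , drop = FALSE] +
    u * (xmin[nbr_pick, , drop = FALSE] - xmin[base_rows, , drop = FALSE])
  out_x <- rbind(xm, synth)
  if (is.data.frame(x)) out_x <- as.data.frame(out_x)
  rownames(out_x) <- NULL
  list(
    x = out_x,
    y = c(y, rep(minority, n_syn)),
    synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_syn)),
    parents = rbind(matrix(NA_integer_, length(y), 2),
                    cbind(min_idx[base_rows], min_idx[nbr_pick]))
  )
}

#' Full preprocessing chain on a raw cohort
#'
#' Encode -> impute -> stratified split -> standardize -> SMOTE(train).
#' The label is `gdm`; generator-internal columns (`risk_score`,
#' `outcome_prob`, `ogtt_tested`) are dropped from the feature set.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param train_fraction,split_seed passed to [stratified_split()].
#' @param smote_k,smote_seed passed to [smote_balance()].
#' @return list with `train_x`, `train_y` (SMOTE-balanced, scaled),
#'   `test_x`, `test_y` (original distribution, scaled), `scaling_params`,
#'   `split` (index bookkeeping), `smote` (synthetic-row bookkeeping), and
#'   `counts` (per-stage class counts).
#' @export
preprocess_cohort <- function(cohort, train_fraction = 0.8, split_seed = 42,
                              smote_k = 5, smote_seed = 42) {
  drop <- intersect(c("risk_score", "outcome_prob", "ogtt_tested"), names(cohort))
  y <- cohort$gdm
  x <- cohort[, setdiff(names(cohort), c(drop, "gdm")), drop = FALSE]
  x <- encode_ethnicity(x)
  x <- impute_ogtt_zero(x)
  split <- stratified_split(x, y, train_fraction, split_seed)
  scaled <- standardize(split$train_x, split$test_x)
  bal <- smote_balance(scaled$train, split$train_y, smote_k, smote_seed)
  list(
    train_x = bal$x, train_y = bal$y,
    test_x = scaled$test, test_y = split$test_y,
    scaling_params = scaled$params,
    split = split[c("idx_train", "idx_test", "split_seed", "train_fraction")],
    smote = bal[c("synthetic", "parents")],
    counts = list(
      n = length(y),
      train = table(split$train_y), test = table(split$test_y),
      train_balanced = table(bal$y)
    )
  )
}
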