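# Preprocessing chain: encoding, imputation, stratified split, train-only
# scaling, SMOTE.

test_that("ethnicity one-hot uses drop-first with African as reference", {
  df <- data.frame(ethnicity = c("African", "Asian", "Other", "Caucasian",
                                 "Hispanic"))
  enc <- encode_ethnicity(df)
  expect_setequal(names(enc), c("ethnicity_Asian", "ethnicity_Caucasian",
                                "ethnicity_Hispanic", "ethnicity_Other"))
  expect_equal(unname(unlist(enc[1, ])), c(0, 0, 0, 0))   # African
  expect_equal(enc$ethnicity_Asian, c(0, 1, 0, 0, 0))
  expect_equal(enc$ethnicity_Other, c(0, 0, 1, 0, 0))
  expect_error(encode_ethnicity(data.frame(ethnicity = "Martian")), "Martian")
})

test_that("zero-imputation fills exactly the missing OGTT cells", {
  df <- data.frame(rbs = c(100, 110), ogtt_fasting = c(NA, 95),
                   ogtt_1h = c(NA, 185), ogtt_2h = c(NA, 150))
  out <- impute_ogtt_zero(df)
  expect_equal(out$ogtt_fasting, c(0, 95))
  expect_equal(out$ogtt_1h, c(0, 185))
  expect_equal(attr(out, "n_imputed"), 3L)
  # identity on complete data
  complete <- data.frame(rbs = 1:3, ogtt_fasting = 4:6, ogtt_1h = 7:9,
                         ogtt_2h = 10:12)
  expect_equal(impute_ogtt_zero(complete)[, ], complete, ignore_attr = TRUE)
  # zeros appear exactly where MISSING was, and only there
  expect_identical(out$ogtt_2h == 0, is.na(df$ogtt_2h))
  expect_error(impute_ogtt_zero(data.frame(rbs = c(NA, 1))), "rbs")
})

test_that("stratified split allocates per class with exact proportionality", {
  x <- data.frame(v = seq_len(100))
  y <- rep(c(0, 1), each = 50)
  sp <- stratified_split(x, y, 0.8, seed = 1)
  expect_identical(length(sp$train_y), 80L)
  expect_identical(sum(sp$train_y == 0), 40L)
  expect_identical(sum(sp$test_y == 1), 10L)
  # conservation: disjoint and exhaustive
  expect_identical(sort(c(sp$idx_train, sp$idx_test)), 1:100)
  # determinism
  sp2 <- stratified_split(x, y, 0.8, seed = 1)
  expect_identical(sp$idx_train, sp2$idx_train)
  expect_error(stratified_split(x[1:3, , drop = FALSE], c(0, 1, 1), 0.8, 1),
               "fewer than 2")
})

test_that("a 10,000-row split yields 8,000/2,000 with proportions within one record", {
  cfg <- gdm_config(n_patients = 10000, seed = 21)
  ch <- generate_cohort(cfg)
  sp <- stratified_split(ch[, c("age", "bmi")], ch$gdm, 0.8, seed = 42)
  expect_identical(length(sp$idx_train), 8000L)
  expect_identical(length(sp$idx_test), 2000L)
  expect_lt(abs(mean(sp$train_y) - mean(ch$gdm)), 1 / 2000)
  expect_lt(abs(mean(sp$test_y) - mean(ch$gdm)), 1 / 2000)
})

test_that("standardization is train-fitted, exact, and leakage-safe", {
  train <- data.frame(age = c(0, 2), family_hx = c(0, 1))
  test <- data.frame(age = 3, family_hx = 1)
  out <- standardize(train, test, features = "age")
  expect_equal(out$train$age * sqrt(2), c(-1, 1))  # hand z-score, sample SD
  expect_equal(out$test$age, (3 - 1) / sd(c(0, 2)))
  expect_identical(out$train$family_hx, c(0, 1))   # binary excluded

  # params depend only on train rows: permuting test leaves them identical
  cfg <- gdm_config(n_patients = 400, seed = 2)
  ch <- encode_ethnicity(generate_cohort(cfg))
  ch <- impute_ogtt_zero(ch[, setdiff(names(ch), c("risk_score", "outcome_prob",
                                                   "ogtt_tested", "gdm"))])
  a <- standardize(ch[1:300, ], ch[301:400, ])
  b <- standardize(ch[1:300, ], ch[sample(301:400), ])
  expect_identical(a$params, b$params)
  # train columns are centered and unit-scaled
  expect_lt(max(abs(colMeans(a$train[, a$params$feature]))), 1e-9)
  expect_lt(max(abs(vapply(a$train[, a$params$feature], sd, 1) - 1)), 1e-9)

  expect_error(standardize(data.frame(k = c(1, 1)), data.frame(k = 1),
                           features = "k"), "k")
})

test_that("SMOTE balances classes by convex minority interpolation", {
  # already balanced: identity
  toy <- make_toy_classification(n = 40, seed = 3)
  y_bal <- rep(c(0, 1), 20)
  out <- smote_balance(toy$x, y_bal, k_neighbors = 3, seed = 1)
  expect_identical(as.matrix(out$x), as.matrix(toy$x))
  expect_identical(out$y, y_bal)

  # two-point minority with k = 1: synthetic points lie on the segment
  x <- data.frame(a = c(0, 1, 5, 6, 7, 8), b = c(0, 1, 5, 6, 7, 8))
  y <- c(1, 1, 0, 0, 0, 0)
  out <- smote_balance(x, y, k_neighbors = 1, seed = 7)
  expect_identical(as.integer(table(out$y)), c(4L, 4L))
  synth <- as.matrix(out$x[out$synthetic, ])
  expect_equal(synth[, "a"], synth[, "b"])          # on the diagonal segment
  expect_true(all(synth[, "a"] >= 0 & synth[, "a"] <= 1))

  # originals preserved verbatim, prepended
  expect_identical(as.matrix(out$x[!out$synthetic, ]), as.matrix(x),
                   ignore_attr = TRUE)

  expect_error(smote_balance(x, y, k_neighbors = 5, seed = 1), "smaller k")
})

test_that("every synthetic row is a convex combination of two minority rows", {
  # exhaustive pair search on a small input (independent of the recorded
  # parent bookkeeping)
  toy <- make_toy_classification(n = 50, seed = 9)
  y <- c(rep(1, 35), rep(0, 15))
  out <- smote_balance(toy$x, y, k_neighbors = 5, seed = 2)
  expect_identical(as.integer(table(out$y)), c(35L, 35L))
  minority <- as.matrix(toy$x[y == 0, ])
  synth <- as.matrix(out$x[out$synthetic, ])
  for (i in seq_len(nrow(synth))) {
    found <- FALSE
    for (a in seq_len(nrow(minority))) {
      for (b in seq_len(nrow(minority))) {
        if (a == b) next
        d <- minority[b, ] - minority[a, ]
        u <- if (any(d != 0)) ((synth[i, ] - minority[a, ]) / d)[which(d != 0)[1]] else 0
        if (u >= 0 && u <= 1 &&
            max(abs(minority[a, ] + u * d - synth[i, ])) < 1e-9) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    expect_true(found)
  }
})

test_that("full preprocessing chain is coherent on a small cohort", {
  cfg <- gdm_config(n_patients = 500, seed = 13)
  ch <- generate_cohort(cfg)
  prep <- preprocess_cohort(ch)
  expect_identical(length(prep$split$idx_train), 400L)
  # balanced training classes
  expect_identical(length(unique(unname(table(prep$train_y)))), 1L)
  # no missing cells anywhere downstream
  expect_false(anyNA(prep$train_x))
  expect_false(anyNA(prep$test_x))
  # test partition keeps the original imbalance
  expect_gt(abs(mean(prep$test_y) - 0.5), 0.05)
})
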