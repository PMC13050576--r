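# Seven-method importance ensemble and consensus ranking.

test_that("correlation importance is maximal for a copy of the outcome and null for noise", {
  set.seed(1)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  x <- data.frame(copy = y, noise = rnorm(n), weak = y + rnorm(n, sd = 3))
  iv <- compute_importance(x, y, "correlation")
  expect_equal(unname(iv$scores["copy"]), 1)
  expect_identical(unname(iv$ranks["copy"]), 1L)
  expect_lt(abs(iv$raw["noise"]), 3 / sqrt(n))
  expect_lt(iv$scores["noise"], 0.05)
  # constant feature: scored 0 with a warning, not an error
  x$flat <- 1
  expect_warning(iv2 <- compute_importance(x, y, "correlation"), "constant")
  expect_equal(unname(iv2$raw["flat"]), 0)
})

test_that("normalized scores live in [0,1] and normalization is idempotent", {
  toy <- make_toy_classification(n = 300, p = 5, seed = 2)
  for (m in c("forest", "f_score", "mutual_information", "correlation",
              "recursive_elimination")) {
    iv <- compute_importance(toy$x, toy$y, m, seed = 3)
    expect_true(all(iv$scores >= 0 & iv$scores <= 1))
    expect_equal(max(iv$scores), 1)
    expect_equal(min(iv$scores), 0)
    expect_identical(sort(unname(iv$ranks)), 1:5)
    # idempotent: re-normalizing the normalized scores changes nothing
    expect_equal(earlygdm:::minmax_normalize(iv$scores), iv$scores,
                 ignore_attr = TRUE)
  }
})

test_that("permutation importance vanishes for a feature the model ignores", {
  set.seed(4)
  n <- 600
  x <- data.frame(signal = rnorm(n), ignored = rnorm(n))
  y <- as.integer(x$signal > 0)
  iv <- compute_importance(x, y, "permutation",
                           options = list(permutation_eval_n = 600), seed = 5)
  expect_lt(abs(iv$raw["ignored"]), 0.02)  # zero within Monte-Carlo noise
  expect_gt(iv$raw["signal"], 0.3)
  # oracle cross-check: refitting without the ignored feature loses nothing
  acc_with <- mean(predict(ranger::ranger(x = x, y = factor(y), num.trees = 100,
                                          seed = 1, num.threads = 1), x)$predictions == y)
  acc_without <- mean(predict(ranger::ranger(x = x[, "signal", drop = FALSE],
                                             y = factor(y), num.trees = 100,
                                             seed = 1, num.threads = 1),
                              x[, "signal", drop = FALSE])$predictions == y)
  expect_lt(abs(acc_with - acc_without), 0.02)
})

test_that("recursive elimination orders features by multivariate signal strength", {
  set.seed(6)
  n <- 800
  x <- data.frame(strong = rnorm(n), medium = rnorm(n), null = rnorm(n))
  y <- as.integer(2 * x$strong + 0.7 * x$medium + rnorm(n) > 0)
  iv <- compute_importance(x, y, "recursive_elimination")
  expect_identical(unname(iv$ranks[c("strong", "medium", "null")]), 1:3)
  # score mapping: (p - rank + 1) / p before normalization
  expect_equal(sort(unname(iv$raw), decreasing = TRUE), c(3, 2, 1) / 3)
})

test_that("mutual information detects nonlinear dependence that correlation misses", {
  set.seed(8)
  n <- 3000
  x <- data.frame(sym = rnorm(n), lin = rnorm(n), noise = rnorm(n))
  y <- as.integer(abs(x$sym) > 0.67)  # symmetric: zero linear correlation
  y <- ifelse(rbinom(n, 1, 0.1) == 1, 1 - y, y)
  x$lin <- x$lin + y
  mi <- compute_importance(x, y, "mutual_information", seed = 9)
  co <- compute_importance(x, y, "correlation")
  expect_gt(mi$raw["sym"], mi$raw["noise"] + 0.05)
  expect_lt(co$scores["sym"], 0.1)     # invisible to linear correlation
  # binary feature uses the exact plug-in estimate
  x2 <- data.frame(flag = y, cont = rnorm(n))
  mi2 <- compute_importance(x2, y, "mutual_information", seed = 9)
  p1 <- mean(y)
  expect_equal(unname(mi2$raw["flag"]),
               -p1 * log(p1) - (1 - p1) * log(1 - p1),
               tolerance = 1e-10)  # MI of a variable with itself = entropy
})

test_that("consensus averages scores and computes rank SDs as specified", {
  iv <- function(method, scores) {
    ranks <- order(order(-scores, names(scores)))
    names(ranks) <- names(scores)
    structure(list(method = method, scores = scores, ranks = ranks,
                   raw = scores), class = "gdm_importance")
  }
  a <- iv("forest", c(A = 1.0, B = 0.8, C = 0.0))
  b <- iv("correlation", c(A = 0.5, B = 1.0, C = 0.0))
  tab <- consensus_rank(list(a, b))
  expect_equal(tab$average[tab$feature == "A"], 0.75)
  expect_equal(tab$average[tab$feature == "B"], 0.9)
  expect_equal(tab$average[tab$feature == "C"], 0)
  expect_identical(tab$feature[1], "B")  # sorted by average, descending
  # ranks (1,2) vs (2,1): sample SD = 0.7071; C agrees at rank 3 -> SD 0
  expect_equal(tab$rank_sd[tab$feature == "A"], sd(c(1, 2)))
  expect_equal(tab$rank_sd[tab$feature == "A"], 0.7071, tolerance = 1e-4)
  expect_equal(tab$rank_sd[tab$feature == "C"], 0)
  # identical vectors: rank SD 0 everywhere
  tab2 <- consensus_rank(list(a, a))
  expect_true(all(tab2$rank_sd == 0))
  # invariant to supply order
  tab_rev <- consensus_rank(list(b, a))
  expect_equal(tab_rev$average, tab$average)
  # mismatched feature sets are rejected with the symmetric difference
  c_bad <- iv("f_score", c(A = 1, B = 0, D = 0.5))
  expect_error(consensus_rank(list(a, c_bad)), "C, D")
  expect_error(consensus_rank(list(a)), "length")
})

test_that("top-k selection applies the average / rank-SD / name tie-breaks", {
  tab <- data.frame(feature = c("A", "B", "C"),
                    average = c(0.9, 0.75, 0.0),
                    rank_sd = c(0, 0, 0))
  expect_identical(select_top_k(tab, 1), "A")
  expect_identical(select_top_k(tab, 3), c("A", "B", "C"))
  tie <- data.frame(feature = c("x", "y"), average = c(0.5, 0.5),
                    rank_sd = c(2.0, 1.0))
  expect_identical(select_top_k(tie, 1), "y")  # lower rank SD wins
  tie2 <- data.frame(feature = c("b", "a"), average = c(0.5, 0.5),
                     rank_sd = c(1, 1))
  expect_identical(select_top_k(tie2, 1), "a")  # then lexicographic
  expect_error(select_top_k(tab, 0), "out of range")
  expect_error(select_top_k(tab, 4), "out of range")
})

test_that("consensus is invariant to method order and affine score rescaling,
           and ranks are invariant to monotone rescaling", {
  toy <- make_toy_classification(n = 250, p = 4, seed = 10)
  iv1 <- compute_importance(toy$x, toy$y, "f_score")
  iv2 <- compute_importance(toy$x, toy$y, "correlation")
  # positive affine transform of raw scores survives min-max normalization
  iv1_scaled <- iv1
  iv1_scaled$raw <- 100 * iv1$raw + 7
  expect_equal(earlygdm:::minmax_normalize(iv1_scaled$raw), iv1$scores,
               ignore_attr = TRUE)
  # strictly monotone (non-affine) transform preserves the rank order
  monotone <- rank(-exp(2 * iv1$raw))
  expect_identical(unname(rank(-iv1$raw)), unname(monotone))
  expect_equal(consensus_rank(list(iv1, iv2))$average,
               consensus_rank(list(iv2, iv1))$average)
})
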