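# Stage 3: seven-method feature-importance ensemble and consensus ranking.
#
# Methods: impurity importance from a random forest and from an
# extra-randomized forest (100 trees each); one-way ANOVA F-scores;
# mutual information (nearest-neighbour estimator for continuous features,
# plug-in for binary ones); permutation importance (accuracy decrease);
# recursive feature elimination on logistic-regression coefficients; and
# absolute Pearson correlation. Every method's raw scores are min-max
# normalized to [0, 1] for comparability before averaging.

IMPORTANCE_METHODS <- c("forest", "extra_random_trees", "f_score",
                        "mutual_information", "permutation",
                        "recursive_elimination", "correlation")

minmax_normalize <- function(s) {
  rng <- range(s)
  if (rng[1] == rng[2]) return(rep(1, length(s)))  # all equal -> all 1
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Per-method feature importance
#'
#' @param x numeric data.frame/matrix of features.
#' @param y binary 0/1 labels.
#' @param method one of `IMPORTANCE_METHODS`.
#' @param options named list of method options: `n_trees` (100),
#'   `permutation_repeats` (10), `permutation_eval_n` (2000; evaluation
#'   subsample for tractability), `mi_k` (3).
#' @param seed RNG seed.
#' @return list of class `gdm_importance`: `method`, normalized `scores`
#'   (named, in `[0,1]`), integer `ranks` (1 = most important, ties broken
#'   by feature-name order), and `raw` scores.
#' @export
compute_importance <- function(x, y, method, options = list(), seed = 42) {
  x <- as.data.frame(x)
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  method <- match.arg(method, IMPORTANCE_METHODS)
  opt <- utils::modifyList(list(n_trees = 100, permutation_repeats = 10,
                                permutation_eval_n = 2000, mi_k = 3), options)
  raw <- switch(
    method,
    forest = ranger::ranger(
      x = x, y = factor(y), num.trees = opt$n_trees, importance = "impurity",
      seed = seed, num.threads = 1)$variable.importance,
    extra_random_trees = ranger::ranger(
      x = x, y = factor(y), num.trees = opt$n_trees, importance = "impurity",
      splitrule = "extratrees", num.random.splits = 1,
      seed = seed, num.threads = 1)$variable.importance,
    f_score = anova_f_scores(x, y),
    mutual_information = mi_scores(x, y, k = opt$mi_k, seed = seed),
    permutation = permutation_importance(x, y, opt, seed),
    recursive_elimination = rfe_scores(x, y),
    correlation = {
      s <- suppressWarnings(abs(as.numeric(stats::cor(as.matrix(x), y))))
      if (anyNA(s)) {
        warning("constant feature(s) under correlation scored 0")
        s[is.na(s)] <- 0
      }
      names(s) <- names(x)
      s
    }
  )
  raw <- raw[names(x)]
  scores <- minmax_normalize(raw)
  names(scores) <- names(x)
  ranks <- order(order(-scores, names(x)))  # deterministic tie-break by name
  names(ranks) <- names(x)
  structure(list(method = method, scores = scores, ranks = ranks, raw = raw),
            class = "gdm_importance")
}

# one-way ANOVA F-statistic of each feature against the binary outcome
anova_f_scores <- function(x, y) {
  xm <- as.matrix(x)
  groups <- split(seq_along(y), y)
  g <- length(groups)
  n <- length(y)
  grand <- colMeans(xm)
  ssb <- 0; ssw <- 0
  for (idx in groups) {
    sub <- xm[idx, , drop = FALSE]
    m <- colMeans(sub)
    ssb <- ssb + length(idx) * (m - grand)^2
    ssw <- ssw + colSums((sub - rep(m, each = length(idx)))^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[ssw == 0] <- 0
  stats::setNames(as.numeric(f), colnames(xm))
}

# Mutual information of each feature with the binary outcome.
# Binary features: plug-in estimate from the 2x2 table. Continuous
# features: nearest-neighbour estimator for a continuous variable against a
# discrete label (distance to the k-th same-class neighbour, then counting
# neighbours in the full sample within that radius), with tiny seeded
# jitter to break ties.
mi_scores <- function(x, y, k = 3, seed = 42) {
  set.seed(stage_seed(seed, "mi_jitter"))
  out <- numeric(ncol(x))
  names(out) <- names(x)
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (all(v %in% c(0, 1))) {
      out[j] <- discrete_mi(v, y)
    } else {
      v <- v + stats::rnorm(length(v)) * 1e-10 * max(1, mean(abs(v)))
      out[j] <- continuous_discrete_mi(v, y, k)
    }
  }
  pmax(out, 0)
}

discrete_mi <- function(v, y) {
  tab <- table(v, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  sum(terms[p > 0])
}

continuous_discrete_mi <- function(v, y, k = 3) {
  n <- length(v)
  classes <- split(seq_len(n), y)
  classes <- classes[lengths(classes) > 1]
  radius <- rep(NA_real_, n)
  kk <- rep(NA_real_, n)
  for (idx in classes) {
    vc <- v[idx]
    ord <- order(vc)
    vs <- vc[ord]
    m <- length(vs)
    k_use <- min(k, m - 1)
    # k-th nearest among the sorted same-class values: candidates are the
    # k_use predecessors and successors of each position
    cand <- matrix(Inf, m, 2 * k_use)
    for (d in seq_len(k_use)) {
      cand[(d + 1):m, d] <- vs[(d + 1):m] - vs[1:(m - d)]
      cand[1:(m - d), k_use + d] <- vs[(1 + d):m] - vs[1:(m - d)]
    }
    kth <- apply(cand, 1, function(r) sort(r)[k_use])
    radius[idx[ord]] <- kth
    kk[idx[ord]] <- k_use
  }
  keep <- !is.na(radius)
  vs_all <- sort(v)
  hi <- findInterval(v[keep] + radius[keep], vs_all, left.open = TRUE)
  lo <- findInterval(v[keep] - radius[keep], vs_all)
  m_i <- pmax(hi - lo - 1, 1)
  label_n <- lengths(split(seq_len(n), y))[as.character(y[keep])]
  mi <- digamma(n) - mean(digamma(as.numeric(label_n))) +
    mean(digamma(kk[keep])) - mean(digamma(m_i))
  max(mi, 0)
}

# accuracy decrease when one feature is shuffled, mean over repeats;
# evaluated on a seeded subsample for tractability
permutation_importance <- function(x, y, opt, seed) {
  yf <- factor(y)
  rf <- ranger::ranger(x = x, y = yf, num.trees = opt$n_trees,
                       seed = seed, num.threads = 1)
  set.seed(stage_seed(seed, "permutation"))
  n_eval <- min(nrow(x), opt$permutation_eval_n)
  eval_idx <- sample.int(nrow(x), n_eval)
  xe <- x[eval_idx, , drop = FALSE]
  ye <- yf[eval_idx]
  baseline <- mean(predict(rf, xe, num.threads = 1)$predictions == ye)
  drops <- numeric(ncol(x))
  for (j in seq_along(x)) {
    acc <- numeric(opt$permutation_repeats)
    for (r in seq_len(opt$permutation_repeats)) {
      xp <- xe
      xp[[j]] <- xp[[j]][sample.int(n_eval)]
      acc[r] <- mean(predict(rf, xp, num.threads = 1)$predictions == ye)
    }
    drops[j] <- baseline - mean(acc)
  }
  stats::setNames(drops, names(x))
}

# backward elimination on standardized logistic-regression coefficients,
# run to completion; rank 1 = last survivor; score = (p - rank + 1) / p
rfe_scores <- function(x, y) {
  xm <- scale(as.matrix(x))
  xm[, attr(xm, "scaled:scale") == 0] <- 0
  p <- ncol(xm)
  remaining <- colnames(xm)
  rank_of <- stats::setNames(integer(p), colnames(xm))
  r <- p
  while (length(remaining) > 1) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, xm[, remaining, drop = FALSE]), y,
                     family = stats::binomial())
    )
    coefs <- abs(fit$coefficients[-1])
    coefs[is.na(coefs)] <- 0
    weakest <- remaining[which.min(coefs)]
    rank_of[weakest] <- r
    remaining <- setdiff(remaining, weakest)
    r <- r - 1
  }
  rank_of[remaining] <- 1L
  (p - rank_of + 1) / p
}

#' Run all seven importance methods
#'
#' @inheritParams compute_importance
#' @param methods subset of `IMPORTANCE_METHODS` (default: all seven).
#' @return named list of `gdm_importance` vectors.
#' @export
importance_ensemble <- function(x, y, methods = IMPORTANCE_METHODS,
                                options = list(), seed = 42) {
  stats::setNames(
    lapply(methods, function(m)
      compute_importance(x, y, m, options, stage_seed(seed, m))),
    methods
  )
}

#' Consensus over per-method importance vectors
#'
#' Average of the normalized scores across methods plus the sample SD of
#' per-method ranks (fractional average ranks used for tied scores).
#' Output sorted by average descending; invariant to the order the vectors
#' are supplied in.
#'
#' @param vectors list of `gdm_importance` objects over identical features.
#' @return data.frame (class `gdm_consensus`) with columns feature,
#'   average, rank_sd, and one `rank_<method>` column per method.
#' @export
consensus_rank <- function(vectors) {
  stopifnot(length(vectors) >= 2)
  feats <- sort(names(vectors[[1]]$scores))
  for (v in vectors) {
    vf <- sort(names(v$scores))
    if (!identical(vf, feats)) {
      stop("mismatched feature sets; symmetric difference: ",
           paste(sort(union(setdiff(vf, feats), setdiff(feats, vf))),
                 collapse = ", "))
    }
  }
  score_mat <- sapply(vectors, function(v) v$scores[feats])
  rank_mat <- apply(score_mat, 2, function(s) rank(-s, ties.method = "average"))
  out <- data.frame(
    feature = feats,
    average = rowMeans(score_mat),
    rank_sd = apply(rank_mat, 1, stats::sd),
    stringsAsFactors = FALSE
  )
  colnames(rank_mat) <- paste0("rank_", vapply(vectors, `[[`, "", "method"))
  out <- cbind(out, rank_mat)
  out <- out[order(-out$average, out$rank_sd, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gdm_consensus", "data.frame")
  out
}

#' Top-k features from a consensus table
#'
#' Highest average importance; ties broken by lower rank SD, then by
#' feature name. Deterministic.
#'
#' @param table a `gdm_consensus`.
#' @param k number of features, `1 <= k <= p`.
#' @return character vector of k feature names, best first.
#' @export
select_top_k <- function(table, k) {
  if (k < 1 || k > nrow(table)) stop("k out of range [1, ", nrow(table), "]")
  ord <- order(-table$average, table$rank_sd, table$feature)
  table$feature[ord][seq_len(k)]
}
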