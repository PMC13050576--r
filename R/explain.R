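# Stage 5: additive per-feature attribution (Kernel SHAP).
#
# Shapley values are estimated by weighted least squares over feature
# coalitions with the Shapley kernel weight; absent features are filled in
# from background rows (interventional masking). The additivity constraint
# (base value + sum of contributions = prediction) is imposed exactly in
# the regression, so local accuracy holds up to numerical precision even
# under coalition sampling. When the full coalition space (2^p - 2) fits in
# the budget it is enumerated with exact kernel weights, which makes the
# estimate the exact Shapley value of the masked-prediction game.

#' Sample background and stratified explain sets from the test partition
#'
#' Background: simple random sample without replacement. Explain set:
#' stratified sample with exactly the requested per-class counts.
#'
#' @param test_x,test_y test features and 0/1 labels.
#' @param n_background background-set size (default 100).
#' @param class_counts named vector `c(positive = ..., negative = ...)` of
#'   explain-set counts per class (default 33 positive / 17 negative).
#' @param seed RNG seed.
#' @return list with `background`, `explain_x`, `explain_y`,
#'   `background_idx`, `explain_idx`.
#' @export
sample_explain_sets <- function(test_x, test_y, n_background = 100,
                                class_counts = c(positive = 33, negative = 17),
                                seed = 42) {
  n <- nrow(test_x)
  stopifnot(n_background <= n)
  n_pos <- sum(test_y == 1); n_neg <- sum(test_y == 0)
  if (class_counts[["positive"]] > n_pos || class_counts[["negative"]] > n_neg) {
    stop("requested explain counts exceed class sizes (",
         n_pos, " positive, ", n_neg, " negative available)")
  }
  set.seed(seed)
  background_idx <- sort(sample.int(n, n_background))
  explain_idx <- c(sample(which(test_y == 1), class_counts[["positive"]]),
                   sample(which(test_y == 0), class_counts[["negative"]]))
  list(background = test_x[background_idx, , drop = FALSE],
       explain_x = test_x[explain_idx, , drop = FALSE],
       explain_y = test_y[explain_idx],
       background_idx = background_idx, explain_idx = explain_idx)
}

# Shapley kernel weight for a coalition of size s among p features
shapley_kernel_weight <- function(p, s) {
  (p - 1) / (choose(p, s) * s * (p - s))
}

# all 0/1 coalition vectors of length p, excluding empty and full
enumerate_coalitions <- function(p) {
  z <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(z) <- NULL
  z[rowSums(z) > 0 & rowSums(z) < p, , drop = FALSE]
}

#' Kernel SHAP attribution
#'
#' @param model a `gdm_model`, a `gdm_mlp`, or a function mapping a feature
#'   matrix to a numeric prediction vector.
#' @param background background data (data.frame/matrix) characterizing the
#'   model's average behaviour; used raw, without clustering.
#' @param instances rows to explain.
#' @param n_coalitions coalition budget per instance (default 2048); must
#'   be at least p + 2. When `2^p - 2 <= n_coalitions` the coalition space
#'   is enumerated and the result is exact.
#' @param seed RNG seed for coalition sampling.
#' @return object of class `gdm_attributions`: `base_value` (expected
#'   prediction over background), `matrix` (instance x feature
#'   contributions), `prediction` per instance, `feature_values`, `exact`.
#' @export
attribute <- function(model, background, instances, n_coalitions = 2048,
                      seed = 42) {
  predict_fun <- if (is.function(model)) {
    model
  } else if (inherits(model, "gdm_mlp")) {
    function(x) predict(model, x)
  } else {
    function(x) predict_prob(model, x)
  }
  background <- as.matrix(background)
  instances <- as.matrix(instances)
  p <- ncol(background)
  stopifnot(ncol(instances) == p, nrow(background) >= 1)
  if (n_coalitions < p + 2) {
    stop("n_coalitions must be at least p + 2 = ", p + 2,
         " (system underdetermined)")
  }
  base_value <- mean(predict_fun(background))
  fx <- as.numeric(predict_fun(instances))

  exact <- (2^p - 2) <= n_coalitions
  if (exact) {
    Z <- enumerate_coalitions(p)
    w <- shapley_kernel_weight(p, rowSums(Z))
  } else {
    set.seed(stage_seed(seed, "coalitions"))
    sizes <- 1:(p - 1)
    size_w <- (p - 1) / (sizes * (p - sizes))     # total kernel mass per size
    # always include all singletons and their complements, then sample the
    # remaining budget from the kernel size distribution
    Z_fix <- rbind(diag(p), 1 - diag(p))
    n_samp <- n_coalitions - nrow(Z_fix)
    samp_sizes <- sample(sizes, n_samp, replace = TRUE, prob = size_w)
    Z_samp <- t(vapply(samp_sizes, function(s) {
      z <- numeric(p); z[sample.int(p, s)] <- 1; z
    }, numeric(p)))
    Z <- rbind(Z_fix, Z_samp)
    # sampled rows follow the kernel distribution, so uniform regression
    # weights; the fixed rows get their relative kernel mass
    w <- c(shapley_kernel_weight(p, rowSums(Z_fix)) /
             mean(shapley_kernel_weight(p, samp_sizes)),
           rep(1, n_samp))
  }

  n_bg <- nrow(background)
  n_coal <- nrow(Z)
  phi <- matrix(NA_real_, nrow(instances), p,
                dimnames = list(NULL, colnames(instances)))
  bg_big <- background[rep(seq_len(n_bg), times = n_coal), , drop = FALSE]
  z_big <- Z[rep(seq_len(n_coal), each = n_bg), , drop = FALSE] == 1
  coal_id <- rep(seq_len(n_coal), each = n_bg)
  for (i in seq_len(nrow(instances))) {
    x_big <- bg_big
    inst_big <- matrix(instances[i, ], nrow(bg_big), p, byrow = TRUE)
    x_big[z_big] <- inst_big[z_big]
    preds <- predict_fun(x_big)
    v <- as.numeric(rowsum(preds, coal_id)) / n_bg
    phi[i, ] <- solve_constrained_wls(Z, v, w, base_value, fx[i])
  }
  structure(list(base_value = base_value, matrix = phi, prediction = fx,
                 feature_values = instances, exact = exact),
            class = "gdm_attributions")
}

# weighted least squares with the additivity constraint
# sum(phi) = fx - base imposed by eliminating the last feature
solve_constrained_wls <- function(Z, v, w, base, fx) {
  p <- ncol(Z)
  ey <- v - base
  if (p == 1) return(fx - base)
  zp <- Z[, p]
  Zr <- Z[, -p, drop = FALSE] - zp
  yr <- ey - zp * (fx - base)
  fit <- stats::lm.wfit(Zr, yr, w)
  phi <- fit$coefficients
  phi[is.na(phi)] <- 0
  c(phi, (fx - base) - sum(phi))
}

#' Global importance: mean absolute contribution per feature
#'
#' @param attributions a `gdm_attributions`.
#' @return data.frame (feature, mean_abs_contribution) sorted descending,
#'   ties by feature name.
#' @export
global_importance <- function(attributions) {
  stopifnot(nrow(attributions$matrix) >= 1)
  m <- colMeans(abs(attributions$matrix))
  out <- data.frame(feature = names(m), mean_abs_contribution = unname(m),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_contribution, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Waterfall ledger for a single explained instance
#'
#' Contributions sorted by absolute value (largest first) with a running
#' cumulative sum from the base value to the final prediction; a
#' machine-readable structure suitable for waterfall plotting.
#'
#' @param attributions a `gdm_attributions`.
#' @param instance row index of the instance to display (default 1).
#' @return list with `base_value`, `steps` (data.frame feature, value,
#'   cumulative), `prediction`.
#' @export
waterfall <- function(attributions, instance = 1) {
  phi <- attributions$matrix[instance, ]
  ord <- order(-abs(phi), names(phi))
  phi <- phi[ord]
  steps <- data.frame(feature = names(phi), value = unname(phi),
                      cumulative = attributions$base_value + cumsum(unname(phi)),
                      stringsAsFactors = FALSE)
  list(base_value = attributions$base_value, steps = steps,
       prediction = attributions$base_value + sum(phi))
}
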