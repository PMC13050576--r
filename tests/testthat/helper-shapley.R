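# Independent brute-force Shapley oracle: direct evaluation of the Shapley
# formula over all subsets, with the same interventional masking game
# (absent features drawn from background rows) the package estimator uses.
# Kept free of any package internals on purpose.

oracle_game_value <- function(predict_fun, instance, background, subset) {
  x <- background
  for (j in subset) x[, j] <- instance[[j]]
  mean(predict_fun(x))
}

oracle_shapley <- function(predict_fun, instance, background) {
  p <- ncol(background)
  phi <- numeric(p)
  all_subsets <- function(v) {
    do.call(c, lapply(0:length(v), function(k)
      combn(v, k, simplify = FALSE)))
  }
  for (j in seq_len(p)) {
    rest <- setdiff(seq_len(p), j)
    for (S in all_subsets(rest)) {
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] +
        w * (oracle_game_value(predict_fun, instance, background, c(S, j)) -
               oracle_game_value(predict_fun, instance, background, S))
    }
  }
  phi
}
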