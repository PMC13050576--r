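# Internal helpers shared across stages.

#' Derive a per-stage RNG seed from a root seed
#'
#' Each pipeline stage draws from its own named substream so that adding or
#' reordering a downstream stage never perturbs the draws of an earlier one.
#' The mapping is a fixed integer hash of the stage name folded into the root
#' seed; results stay below 2^31 - 1.
#'
#' @param root integer root seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 2654435.0) %% 2147483647
  as.integer((abs(root) * 7919 + h) %% 2147483647)
}

# clip values to [lo, hi]; boundary mass is accepted (documented behaviour,
# preferred over rejection resampling for simplicity)
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Normal draw clipped (censored) to a range
rnorm_clipped <- function(n, mean, sd, range) {
  clip(stats::rnorm(n, mean, sd), range[1], range[2])
}

# Gumbel(0, scale) draws, used for noisy top-fraction selection
rgumbel <- function(n, scale = 1) {
  -scale * log(-log(stats::runif(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
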