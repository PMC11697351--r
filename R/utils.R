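#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish dialect problems
# (wrong file shape) from validation problems (values out of contract).

err_dialect <- function(msg) {
  stop(errorCondition(msg, class = c("panffpe_dialect_error", "error", "condition")))
}

err_validation <- function(msg) {
  stop(errorCondition(msg, class = c("panffpe_validation_error", "error", "condition")))
}

err_nodata <- function(msg) {
  stop(errorCondition(msg, class = c("panffpe_nodata_error", "error", "condition")))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages of the pipeline draw from streams seeded as
#' `(seed + 7919 * k) mod (2^31 - 1)` for stage index `k`, so a single master
#' seed reproduces every stage while stages stay decoupled.
#'
#' @param seed master integer seed
#' @param k non-negative stream index
#' @return an integer seed valid for [set.seed()]
#' @export
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}

# sample standard deviation based coefficient of variation, in percent
cov_pct <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) err_validation("CoV undefined for groups of size < 2")
  m <- mean(x)
  if (m == 0) err_validation("CoV undefined for zero mean")
  100 * stats::sd(x) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
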