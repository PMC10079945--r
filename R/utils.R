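#' Round half away from zero
#'
#' Deterministic half-up rounding used for amplitude-to-row quantization and
#' for formatting percentages, avoiding base R's round-half-to-even rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; each stage
#' (simulation, balancing, splitting, training, ...) receives its own derived
#' seed so stages can be re-run independently yet reproducibly. The derivation
#' hashes the stage name with a multiplicative congruential mix and folds the
#' result into the 31-bit positive integer range.
#'
#' @param seed master seed (integer).
#' @param stage character stage tag, e.g. `"simulate-1"`, `"split"`.
#' @return a positive integer seed < 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 69069 + h * 2654435 + 1) %% 2147483647)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
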