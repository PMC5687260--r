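# Internal helpers: condition classes, report rounding, scoped RNG.

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("codbench_validation_error", "codbench_error")))
}

stop_precondition <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("codbench_precondition_error", "codbench_error")))
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up, as used in printed report tables
#' (base [round()] rounds half to even, which disagrees with how published
#' percentage tables are typically rounded: the mean of a column whose exact
#' mean is 3.25 prints as 3.3, not 3.2).
#'
#' @param x numeric vector (non-negative in report use).
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves up.
#' @examples
#' round_half_up(3.25, 1)  # 3.3
#' round(3.25, 1)          # 3.2 (banker's)
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  # nudge guards against binary representation of exact halves (e.g. 71.85)
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Unweighted mean of percentages, rounded for reporting
#'
#' The "mean row" computation of the concordance report: an unweighted mean
#' of per-hospital percentages, rounded half-up to one decimal.
#'
#' @param x numeric vector of percentages.
#' @param digits decimal places (default 1, report style).
#' @return length-1 numeric.
#' @examples
#' pct_mean(c(44, 50, 44, 41, 65, 45.8, 52.4, 24))  # 45.8
#' @export
pct_mean <- function(x, digits = 1) {
  round_half_up(mean(x), digits)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Derive a stream seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + index * 7919) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
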