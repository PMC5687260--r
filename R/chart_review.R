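# Chart-review sampling: exact-binomial sample sizes, reproducible random
# draws, and chart-availability attrition.

#' Exact one-sample binomial sample size
#'
#' Smallest n for which the exact one-sided binomial test of
#' H0: p = `p0` against H1: p = `p_alt` (> `p0`) attains the requested power
#' at level `alpha`. For each n the critical count is the smallest x with
#' `P(X >= x | p0) <= alpha`; power is `P(X >= x_crit | p_alt)`. Exact
#' binomial power is sawtoothed in n, so "smallest n meeting power" is the
#' defined rule.
#'
#' Defaults target detection of at least a 20% death-certificate completion
#' error rate against a 5% baseline, giving n = 27 per hospital.
#'
#' @param p0 baseline error proportion under H0.
#' @param p_alt detectable error proportion under H1 (`p_alt > p0`).
#' @param alpha one-sided significance level (default 0.05).
#' @param power requested power (default 0.80).
#' @param n_max search bound (default 10000).
#' @return integer sample size.
#' @examples
#' chart_sample_size()                      # 27
#' chart_sample_size(p0 = 0, p_alt = 1)     # 1
#' @export
chart_sample_size <- function(p0 = 0.05, p_alt = 0.20,
                              alpha = 0.05, power = 0.80,
                              n_max = 10000L) {
  if (!(p0 >= 0 && p0 < p_alt && p_alt <= 1))
    stop_validation("need 0 <= p0 < p_alt <= 1 (got p0 = %g, p_alt = %g)", p0, p_alt)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_validation("'alpha' and 'power' must be in (0, 1)")
  for (n in seq_len(n_max)) {
    upper_tail <- 1 - pbinom((0:n) - 1, n, p0)  # P(X >= x) for x = 0..n
    x_crit <- which(upper_tail <= alpha)[1] - 1L  # smallest such x (maybe n+1)
    if (is.na(x_crit)) x_crit <- n + 1L
    pw <- 1 - pbinom(x_crit - 1, n, p_alt)
    if (pw >= power) return(n)
  }
  stop_precondition("no n <= %d attains power %g", n_max, power)
}

#' Draw a reproducible chart-review sample
#'
#' Uniform simple random sample of deaths without replacement, reproducible
#' from the seed. The caller's RNG state is untouched.
#'
#' @param death_ids vector of death identifiers.
#' @param n sample size, `n <= length(death_ids)`.
#' @param seed integer seed.
#' @return vector of `n` sampled ids (in draw order).
#' @export
draw_chart_sample <- function(death_ids, n, seed) {
  if (n > length(death_ids))
    stop_precondition("sample size %d exceeds the %d eligible deaths",
                      n, length(death_ids))
  if (n < 0) stop_validation("'n' must be non-negative")
  with_seed(seed, death_ids[sample.int(length(death_ids), n)])
}

#' Apply chart availability to a drawn sample
#'
#' Restricts a drawn sample to the charts actually available for review
#' (complete-case: unavailable charts are dropped, never imputed), and
#' records the sampling plan. Availability is either a per-record logical
#' vector aligned with (or named by) the sample, or a global Bernoulli rate
#' with a seed.
#'
#' @param sample vector of sampled death ids.
#' @param availability logical vector (length of `sample`, or named covering
#'   it) or a single rate in `[0, 1]`.
#' @param seed seed for Bernoulli availability (required when `availability`
#'   is a rate and `sample` is non-empty).
#' @param hospital_id,eligible_deaths,n_target optional bookkeeping recorded
#'   in the plan.
#' @return list with `reviewed` (available subset, draw order preserved) and
#'   `plan`, a one-row data.frame with `hospital_id`, `eligible_deaths`,
#'   `n_target`, `n_drawn`, `n_reviewed`, `pct_reviewed`
#'   (`round(100 n_reviewed / n_drawn)`), `seed`.
#' @examples
#' # 181 of 205 charts available: 88% reviewed
#' r <- apply_availability(paste0("d", 1:205),
#'                         c(rep(TRUE, 181), rep(FALSE, 24)))
#' r$plan$pct_reviewed
#' @export
apply_availability <- function(sample, availability, seed = NULL,
                               hospital_id = NA_character_,
                               eligible_deaths = NA_integer_,
                               n_target = NA_integer_) {
  n_drawn <- length(sample)
  if (is.logical(availability)) {
    if (!is.null(names(availability))) {
      missing <- setdiff(as.character(sample), names(availability))
      if (length(missing))
        stop_validation("no availability flag for death '%s'", missing[1])
      avail <- unname(availability[as.character(sample)])
    } else {
      if (length(availability) != n_drawn)
        stop_validation("availability flags (%d) do not cover the sample (%d)",
                        length(availability), n_drawn)
      avail <- availability
    }
    if (any(is.na(avail))) stop_validation("availability flags contain NA")
  } else if (is.numeric(availability) && length(availability) == 1L) {
    if (is.na(availability) || availability < 0 || availability > 1)
      stop_validation("availability rate must be in [0, 1]")
    if (n_drawn > 0 && is.null(seed))
      stop_validation("a seed is required for rate-based availability")
    avail <- if (n_drawn) with_seed(seed, runif(n_drawn) < availability) else logical(0)
  } else {
    stop_validation("'availability' must be a logical vector or a single rate")
  }
  reviewed <- sample[avail]
  if (n_drawn > 0 && length(reviewed) == 0)
    warning(sprintf("no charts available for review%s",
                    if (is.na(hospital_id)) "" else paste0(" at hospital ", hospital_id)),
            call. = FALSE)
  plan <- data.frame(hospital_id = hospital_id,
                     eligible_deaths = eligible_deaths,
                     n_target = n_target,
                     n_drawn = n_drawn,
                     n_reviewed = length(reviewed),
                     pct_reviewed = if (n_drawn > 0)
                       round_half_up(100 * length(reviewed) / n_drawn) else NA_real_,
                     seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
                     stringsAsFactors = FALSE)
  list(reviewed = reviewed, plan = plan)
}
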