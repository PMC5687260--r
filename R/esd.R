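# Rosner's generalized extreme Studentized deviate (ESD) multi-outlier test
# and the Shapiro-Wilk normality re-check applied to the cleaned rate set.

#' Generalized extreme Studentized deviate (ESD) multi-outlier test
#'
#' Rosner's iterative procedure for up to `k_max` outliers in an approximately
#' normal univariate sample. At step i the remaining value farthest from the
#' mean in studentized units is removed and its deviation
#' `R_i = max |x - mean| / s` recorded; `R_i` is compared against the critical
#' value `lambda_i = (n - i) * t / sqrt((n - i - 1 + t^2) * (n - i + 1))`,
#' where `t` is the Student-t quantile at `p = 1 - alpha / (2 (n - i + 1))`
#' (two-sided; `1 - alpha / (n - i + 1)` one-sided) on `n - i - 1` degrees of
#' freedom. The declared number of outliers is the largest i with
#' `R_i > lambda_i` (Rosner's rule), which makes the procedure robust to
#' masking as long as `k_max` is at least the true outlier count.
#'
#' If the remaining sample becomes constant (sample SD 0) the procedure stops
#' early and declares no further outliers: constant data are legitimately
#' outlier-free.
#'
#' @param values numeric vector, length `n >= k_max + 2`.
#' @param ids identifiers for the values; defaults to `names(values)` or
#'   positional labels.
#' @param k_max maximum number of outliers tested; default
#'   `max(1, floor(0.2 * n))`, a conventional cap.
#' @param alpha significance level (default 0.1, the level used for
#'   death-rate screening).
#' @param two_sided logical; two-sided test by default.
#' @return object of class `esd_result`: list with `tested_k`, `statistics`
#'   (`R_i`), `critical_values` (`lambda_i`), `removed_ids` (order of
#'   removal), `n_outliers`, `outlier_ids`, `alpha`, `two_sided`, `n`.
#' @references Rosner, B. (1983). Percentage points for a generalized ESD
#'   many-outlier procedure. Technometrics 25(2), 165-172.
#' @examples
#' generalized_esd(c(1, 2, 3, 4, 100), k_max = 1)$outlier_ids
#' @export
generalized_esd <- function(values,
                            ids = NULL,
                            k_max = max(1L, floor(0.2 * length(values))),
                            alpha = 0.1,
                            two_sided = TRUE) {
  n <- length(values)
  if (is.null(ids)) ids <- names(values) %||% as.character(seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop_validation("'ids' must match 'values' in length")
  if (any(is.na(values))) stop_validation("'values' must not contain NA")
  if (!is.numeric(k_max) || k_max < 1) stop_precondition("'k_max' must be >= 1")
  k_max <- as.integer(k_max)
  if (n < k_max + 2)
    stop_precondition("need at least k_max + 2 = %d values, got %d", k_max + 2, n)
  if (alpha <= 0 || alpha >= 1) stop_validation("'alpha' must be in (0, 1)")

  x <- values
  keep_ids <- ids
  R <- lambda <- numeric(0)
  removed <- character(0)
  for (i in seq_len(k_max)) {
    m <- mean(x)
    s <- sd(x)
    if (s == 0) break  # constant remainder: no further outliers
    dev <- abs(x - m) / s
    j <- which.max(dev)  # ties: first in input order (deterministic)
    R <- c(R, unname(dev[j]))
    ni <- n - i + 1  # sample size at this step
    p <- if (two_sided) 1 - alpha / (2 * ni) else 1 - alpha / ni
    df <- ni - 2
    tq <- qt(p, df)
    lambda <- c(lambda, (ni - 1) * tq / sqrt((df + tq^2) * ni))
    removed <- c(removed, keep_ids[j])
    x <- x[-j]
    keep_ids <- keep_ids[-j]
  }
  exceed <- which(R > lambda)
  n_outliers <- if (length(exceed)) max(exceed) else 0L
  structure(list(tested_k = length(R),
                 statistics = R,
                 critical_values = lambda,
                 removed_ids = removed,
                 n_outliers = as.integer(n_outliers),
                 outlier_ids = removed[seq_len(n_outliers)],
                 alpha = alpha,
                 two_sided = two_sided,
                 n = n),
            class = "esd_result")
}

#' @export
print.esd_result <- function(x, ...) {
  cat(sprintf("<esd_result> n = %d, tested up to %d outlier(s), alpha = %g (%s)\n",
              x$n, x$tested_k, x$alpha,
              if (x$two_sided) "two-sided" else "one-sided"))
  if (x$tested_k > 0) {
    tab <- data.frame(step = seq_len(x$tested_k),
                      removed = x$removed_ids,
                      R = round(x$statistics, 4),
                      lambda = round(x$critical_values, 4),
                      exceeds = x$statistics > x$critical_values)
    print(tab, row.names = FALSE)
  }
  cat(sprintf("declared outliers: %d%s\n", x$n_outliers,
              if (x$n_outliers) paste0(" (", paste(x$outlier_ids, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Re-tests the outlier-cleaned ("normalized") rate set for normality. In the
#' screening pipeline a failed check is surfaced as a warning, not an error:
#' the tolerance zone is still built, but its +/- 2 SD coverage interpretation
#' is weakened.
#'
#' @param values numeric vector, `3 <= n <= 5000`.
#' @param alpha significance level (default 0.05).
#' @return object of class `normality_result`: list with `W`, `p_value`,
#'   `alpha`, `passed` (`p_value >= alpha`), `n`.
#' @export
normality_check <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 5000)
    stop_precondition("Shapiro-Wilk requires 3 <= n <= 5000, got %d", n)
  if (sd(values) == 0)
    stop_precondition("all values are identical; normality is undefined")
  sw <- shapiro.test(values)
  structure(list(W = unname(sw$statistic),
                 p_value = sw$p.value,
                 alpha = alpha,
                 passed = sw$p.value >= alpha,
                 n = n),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("<normality_result> W = %.5f, p = %.4g, %s at alpha = %g (n = %d)\n",
              x$W, x$p_value, if (x$passed) "passed" else "FAILED",
              x$alpha, x$n))
  invisible(x)
}
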