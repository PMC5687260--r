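# Certificate vs chart-review concordance: paired records, per-hospital
# inaccuracy tables, McNemar tests on discordant pairs, and matched-pair
# (conditional) odds ratios.

#' Build matched certificate/chart pairs
#'
#' Classifies each reviewed death's certificate ICD-10 code into a cause
#' category and pairs it with the chart-review (gold standard) category.
#' Records whose chart review yielded insufficient information are excluded
#' from the pairs and counted (complete-case handling).
#'
#' @param records data.frame with columns `hospital_id`, `death_id`,
#'   `dc_icd10`, `chart_category`.
#' @param codesets category definitions for [classify_cause()].
#' @param insufficient_label chart label marking unreviewable records
#'   (default `"insufficient"`).
#' @return data.frame of pairs (`hospital_id`, `death_id`, `dc_icd10`,
#'   `dc_category`, `chart_category`) with attribute `n_insufficient`.
#' @export
build_pairs <- function(records, codesets = default_codesets(),
                        insufficient_label = "insufficient") {
  required <- c("hospital_id", "death_id", "dc_icd10", "chart_category")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop_validation("records missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(records) == 0) {
    out <- data.frame(hospital_id = character(0), death_id = character(0),
                      dc_icd10 = character(0), dc_category = character(0),
                      chart_category = character(0), stringsAsFactors = FALSE)
    attr(out, "n_insufficient") <- 0L
    return(out)
  }
  if (any(is.na(records$dc_icd10)) || any(is.na(records$chart_category)))
    stop_validation("records contain missing certificate codes or chart categories")
  insufficient <- records$chart_category == insufficient_label
  kept <- records[!insufficient, , drop = FALSE]
  bad <- setdiff(unique(kept$chart_category), cause_categories())
  if (length(bad))
    stop_validation("unknown chart category '%s'", bad[1])
  out <- data.frame(hospital_id = as.character(kept$hospital_id),
                    death_id = as.character(kept$death_id),
                    dc_icd10 = as.character(kept$dc_icd10),
                    dc_category = classify_cause(as.character(kept$dc_icd10), codesets),
                    chart_category = as.character(kept$chart_category),
                    stringsAsFactors = FALSE)
  attr(out, "n_insufficient") <- sum(insufficient)
  out
}

#' Per-hospital concordance table
#'
#' Summarises certificate/chart agreement per hospital in the style of a
#' published audit table: the percentage of reviewed certificates whose cause
#' category disagrees with the chart review, and — among those inaccurate
#' certificates — the percentage certified as each audited cause. Per-cause
#' columns therefore sum to at most 100 within a hospital (the remainder was
#' certified as "other"). A final unweighted mean row averages the
#' per-hospital percentages ([pct_mean()]); all percentages are reported to
#' one decimal, halves up.
#'
#' @param pairs output of [build_pairs()].
#' @param causes per-cause columns to report (default the three audited
#'   disease categories).
#' @return data.frame with one row per hospital plus a `"(mean)"` row;
#'   columns `hospital_id`, `n_reviewed`, `n_inaccurate`, `pct_inaccurate`,
#'   and `pct_<cause>` for each requested cause.
#' @export
concordance_table <- function(pairs, causes = DISEASE_CATEGORIES) {
  if (nrow(pairs) == 0)
    stop_precondition("no reviewed pairs to summarise")
  hospitals <- sort(unique(pairs$hospital_id))
  rows <- lapply(hospitals, function(h) {
    p <- pairs[pairs$hospital_id == h, ]
    n <- nrow(p)
    disc <- p$dc_category != p$chart_category
    ni <- sum(disc)
    row <- data.frame(hospital_id = h, n_reviewed = n, n_inaccurate = ni,
                      pct_inaccurate = round_half_up(100 * ni / n, 1),
                      stringsAsFactors = FALSE)
    for (cause in causes) {
      pc <- if (ni > 0) 100 * sum(disc & p$dc_category == cause) / ni else 0
      row[[paste0("pct_", cause)]] <- round_half_up(pc, 1)
    }
    row
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(hospital_id = "(mean)",
                         n_reviewed = NA_integer_, n_inaccurate = NA_integer_,
                         pct_inaccurate = pct_mean(out$pct_inaccurate),
                         stringsAsFactors = FALSE)
  for (cause in causes)
    mean_row[[paste0("pct_", cause)]] <- pct_mean(out[[paste0("pct_", cause)]])
  out <- rbind(out, mean_row)
  rownames(out) <- NULL
  out
}

#' Discordant-pair counts for one cause
#'
#' For a cause X, counts the two kinds of disagreement in the matched pairs:
#' `b` = certificate says X but the chart does not (overreporting of X),
#' `c` = chart says X but the certificate does not (underreporting of X).
#'
#' @param pairs output of [build_pairs()].
#' @param cause one of [cause_categories()].
#' @return object of class `discordant_pair`: list with `cause`, `b`, `c`.
#' @export
discordant_counts <- function(pairs, cause) {
  cause <- match.arg(cause, cause_categories())
  structure(list(cause = cause,
                 b = sum(pairs$dc_category == cause & pairs$chart_category != cause),
                 c = sum(pairs$chart_category == cause & pairs$dc_category != cause)),
            class = "discordant_pair")
}

unpack_bc <- function(b, c) {
  if (inherits(b, "discordant_pair")) {
    list(b = b$b, c = b$c)
  } else {
    if (is.null(c)) stop_validation("supply a discordant_pair or both b and c")
    if (b < 0 || c < 0) stop_validation("counts must be non-negative")
    list(b = b, c = c)
  }
}

#' McNemar test on discordant pairs
#'
#' Tests marginal symmetry of paired cause assignments from the discordant
#' counts. The exact test (default, appropriate for the small discordant
#' counts chart reviews produce) uses the two-sided binomial tail:
#' `p = min(1, 2 P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`. The
#' asymptotic test uses the chi-squared statistic `(b - c)^2 / (b + c)` on
#' 1 df (no continuity correction).
#'
#' @param b a [discordant_counts()] result, or the count of
#'   certificate-only assignments.
#' @param c chart-only count (when `b` is given as a count).
#' @param exact logical; exact binomial test (default) or asymptotic.
#' @param alpha significance level recorded in the result (default 0.05).
#' @return object of class `mcnemar_result`: list with `b`, `c`, `statistic`
#'   (`(b - c)^2 / (b + c)`, `NA` when `b + c = 0`), `p_value`, `method`,
#'   `alpha`, `significant`.
#' @examples
#' mcnemar_test(10, 2)$p_value  # 2 * pbinom(2, 12, 0.5) = 158/4096
#' @export
mcnemar_test <- function(b, c = NULL, exact = TRUE, alpha = 0.05) {
  bc <- unpack_bc(b, c)
  b <- bc$b; c <- bc$c
  n <- b + c
  statistic <- if (n > 0) (b - c)^2 / n else NA_real_
  if (exact) {
    p <- if (n == 0) 1 else min(1, 2 * pbinom(min(b, c), n, 0.5))
    method <- "exact"
  } else {
    if (n == 0)
      stop_precondition("asymptotic McNemar requires b + c >= 1")
    p <- pchisq(statistic, df = 1, lower.tail = FALSE)
    method <- "asymptotic"
  }
  structure(list(b = b, c = c, statistic = statistic, p_value = p,
                 method = method, alpha = alpha, significant = p < alpha),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar_result> b = %d, c = %d, %s p = %.4g%s\n",
              x$b, x$c, x$method, x$p_value,
              if (x$significant) sprintf(" (significant at %g)", x$alpha) else ""))
  invisible(x)
}

#' Matched-pair (conditional) odds ratio
#'
#' The conditional odds ratio for paired binary data, `OR = b / c`, with a
#' confidence interval from the conditional binomial model of
#' `b | b + c ~ Binomial(b + c, OR / (1 + OR))`:
#' `"exact"` (default) transforms the Clopper-Pearson interval for the
#' binomial proportion, `"lognormal"` uses
#' `exp(log(b/c) +/- z sqrt(1/b + 1/c))`. With `correction = TRUE`, 0.5 is
#' added to both counts for the point estimate (and the log-normal CI),
#' allowing zero cells; the exact CI always uses the raw counts (its bounds
#' are well defined at zero: 0 and `Inf`).
#'
#' @param b a [discordant_counts()] result or the overreport count.
#' @param c underreport count (when `b` is a count).
#' @param level confidence level (default 0.95).
#' @param method `"exact"` or `"lognormal"`.
#' @param correction logical; add 0.5 to both counts (default `FALSE`).
#' @return object of class `odds_ratio_result`: list with `b`, `c`, `or`,
#'   `ci_low`, `ci_high`, `level`, `method`, `correction`.
#' @examples
#' matched_odds_ratio(10, 2)$or                      # 5
#' matched_odds_ratio(12, 0, correction = TRUE)$or   # 25
#' @export
matched_odds_ratio <- function(b, c = NULL, level = 0.95,
                               method = c("exact", "lognormal"),
                               correction = FALSE) {
  method <- match.arg(method)
  bc <- unpack_bc(b, c)
  b <- bc$b; c <- bc$c
  if (b == 0 && c == 0)
    stop_precondition("no discordant pairs: odds ratio undefined")
  if (c == 0 && !correction)
    stop_precondition("c = 0: enable 'correction' for a finite point estimate")
  bb <- b + 0.5 * correction
  cc <- c + 0.5 * correction
  or <- bb / cc
  a2 <- (1 - level) / 2
  if (method == "exact") {
    # Clopper-Pearson for p = b/(b+c), mapped through p/(1-p)
    n <- b + c
    p_low <- if (b == 0) 0 else qbeta(a2, b, c + 1)
    p_high <- if (b == n) 1 else qbeta(1 - a2, b + 1, c)
    ci_low <- p_low / (1 - p_low)
    ci_high <- if (p_high >= 1) Inf else p_high / (1 - p_high)
  } else {
    if ((bb == 0 || cc == 0))
      stop_precondition("log-normal CI needs positive (possibly corrected) counts")
    z <- qnorm(1 - a2)
    se <- sqrt(1 / bb + 1 / cc)
    ci_low <- exp(log(or) - z * se)
    ci_high <- exp(log(or) + z * se)
  }
  structure(list(b = b, c = c, or = or, ci_low = ci_low, ci_high = ci_high,
                 level = level, method = method, correction = correction),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("<odds_ratio_result> OR = %.3g (%g%% CI %.3g-%.3g, %s%s) b = %d, c = %d\n",
              x$or, 100 * x$level, x$ci_low, x$ci_high, x$method,
              if (x$correction) ", corrected" else "", x$b, x$c))
  invisible(x)
}

#' Over/under-reporting direction report by cause
#'
#' For each cause (pooled, or within groups of a column of `pairs`), computes
#' the discordant counts, McNemar test, matched odds ratio, and the reporting
#' direction: `"overreport"` when the certificate claims the cause more often
#' than the chart (`b > c`), `"underreport"` when `b < c`, `"none"` on ties.
#' Zero cells get the 0.5 continuity correction for the OR point estimate;
#' causes with no discordant pairs get `OR = NA`.
#'
#' @param pairs output of [build_pairs()].
#' @param by optional column of `pairs` to group by (e.g. `"hospital_id"`);
#'   `NULL` (default) pools everything.
#' @param causes causes to report (default the three audited categories).
#' @param exact,alpha passed to [mcnemar_test()].
#' @param level,or_method passed to [matched_odds_ratio()].
#' @return data.frame with columns `group`, `cause`, `b`, `c`, `statistic`,
#'   `p_value`, `or`, `ci_low`, `ci_high`, `direction`, `significant`.
#' @export
cause_direction_report <- function(pairs, by = NULL,
                                   causes = DISEASE_CATEGORIES,
                                   exact = TRUE, alpha = 0.05,
                                   level = 0.95, or_method = "exact") {
  groups <- if (is.null(by)) {
    list(`(pooled)` = pairs)
  } else {
    if (!by %in% names(pairs)) stop_validation("no column '%s' in pairs", by)
    split(pairs, pairs[[by]])
  }
  rows <- list()
  for (g in names(groups)) {
    for (cause in causes) {
      dp <- discordant_counts(groups[[g]], cause)
      mc <- mcnemar_test(dp, exact = exact, alpha = alpha)
      or <- if (dp$b + dp$c == 0) {
        list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      } else {
        matched_odds_ratio(dp, level = level, method = or_method,
                           correction = dp$b == 0 || dp$c == 0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, cause = cause, b = dp$b, c = dp$c,
        statistic = mc$statistic, p_value = mc$p_value,
        or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
        direction = if (dp$b > dp$c) "overreport"
                    else if (dp$b < dp$c) "underreport" else "none",
        significant = mc$significant,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
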