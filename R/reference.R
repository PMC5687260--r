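# Published reference figures shipped with the package.

#' Published audit summary figures
#'
#' Per-hospital summary percentages from a published state-wide audit of
#' cause-of-death reporting at eight metro-area hospitals (2009-2012),
#' provided as reference inputs: the number of charts selected and reviewed
#' per hospital, the percentage of reviewed certificates with an inaccurate
#' underlying cause, and — among the inaccurate certificates — the
#' percentage certified as heart disease, cancer, and renal disease. Feeding
#' the percentage columns through [pct_mean()] reproduces the audit's
#' published mean row (45.8 / 71.9 / 3.3 / 17.3).
#'
#' @return data.frame with columns `hospital`, `n_selected`, `n_reviewed`,
#'   `pct_inaccurate`, `pct_heart`, `pct_cancer`, `pct_renal`.
#' @export
audit_reference <- function() {
  data.frame(
    hospital = LETTERS[1:8],
    n_selected = c(18, 26, 25, 22, 20, 33, 31, 30),
    n_reviewed = c(18, 26, 25, 22, 20, 24, 21, 25),
    pct_inaccurate = c(44.0, 50.0, 44.0, 41.0, 65.0, 45.8, 52.4, 24.0),
    pct_heart = c(75.0, 85.0, 81.8, 56.0, 85.0, 54.5, 54.5, 83.0),
    pct_cancer = c(0, 0, 9.0, 0, 8.0, 9.0, 0, 0),
    pct_renal = c(25.0, 15.0, 9.0, 44.0, 0, 27.0, 18.0, 0),
    stringsAsFactors = FALSE)
}

#' Published benchmark zone upper bounds
#'
#' The published benchmark and "+2 SD" zone-ceiling pairs (percent):
#' heart 3.5 (5.9), cancer 4.4 (13.7), renal 3.1 (7.4), all-cause 2.0 (3.3).
#' The implied SDs of the normalized hospital rate sets are half the
#' difference. Useful as an internal consistency check of
#' [tolerance_zone()]; the underlying hospital rates are not public.
#'
#' @return data.frame with columns `category`, `benchmark_rate`, `zone_high`.
#' @export
benchmark_reference <- function() {
  data.frame(category = c("heart", "cancer", "renal", "all_cause"),
             benchmark_rate = c(3.5, 4.4, 3.1, 2.0),
             zone_high = c(5.9, 13.7, 7.4, 3.3),
             stringsAsFactors = FALSE)
}
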