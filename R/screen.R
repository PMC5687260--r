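# The hospital-selection screening algorithm: per-category ESD outlier
# removal, normality re-check, tolerance-zone flagging, and selection of the
# flagged hospitals that contribute the most deaths.

#' Screen hospitals against benchmark tolerance zones
#'
#' Runs the full selection algorithm on a cohort of hospital rates:
#'
#' 1. [generalized_esd()] on each disease category's rates (heart, cancer,
#'    renal); the union of the per-category outliers is removed.
#' 2. The remaining ("normalized") rates in each category are re-checked for
#'    normality with [normality_check()]; failures are recorded and warned
#'    about, but do not stop the pipeline.
#' 3. The per-category SD of the normalized rates builds a
#'    [tolerance_zone()] around each externally supplied benchmark
#'    (per-category SDs are used because zone widths differ by category).
#' 4. Hospitals with a rate at or above `zone_high` (and strictly above the
#'    benchmark, so a zero-width zone around constant rates flags nothing) in
#'    **any** disease category are flagged. The low side is reported but
#'    never flags.
#'
#' An all-cause zone (total deaths / total hospitalizations) is computed over
#' the normalized set for reporting, but all-cause rates neither feed the ESD
#' step nor flag hospitals.
#'
#' @param rates a [hospital_rates()] table covering every disease category for
#'   every hospital.
#' @param benchmarks named numeric vector of benchmark rates (percent) with
#'   elements `heart`, `cancer`, `renal` and optionally `all_cause`;
#'   default [default_benchmarks()].
#' @param k_max maximum outliers tested per category; `NULL` (default) uses
#'   the [generalized_esd()] default `max(1, floor(0.2 n))`.
#' @param esd_alpha ESD significance level (default 0.1).
#' @param sw_alpha Shapiro-Wilk significance level (default 0.05).
#' @return object of class `screen_result`: list with
#'   `outlier_hospitals` (union, in removal order), `esd` (per-category
#'   [esd_result][generalized_esd]), `normalized_set`, `normality`
#'   (per-category), `benchmarks` (data.frame with `category`,
#'   `benchmark_rate`, `sd`, `zone_low`, `zone_high`), `flag_table`
#'   (per hospital x category rates and outside-zone indicator over the
#'   normalized set), `flagged`, `warnings`.
#' @export
screen_hospitals <- function(rates,
                             benchmarks = default_benchmarks(),
                             k_max = NULL,
                             esd_alpha = 0.1,
                             sw_alpha = 0.05) {
  if (!inherits(rates, "hospital_rates")) rates <- hospital_rates(rates)
  ids <- unique(rates$hospital_id)
  for (cat_ in DISEASE_CATEGORIES) {
    have <- rates$hospital_id[rates$category == cat_]
    if (!setequal(have, ids))
      stop_validation("every hospital needs a '%s' rate row", cat_)
  }
  missing_bm <- setdiff(DISEASE_CATEGORIES, names(benchmarks))
  if (length(missing_bm))
    stop_validation("benchmarks missing for: %s", paste(missing_bm, collapse = ", "))

  # 1. per-category ESD; union of outliers
  esd <- list()
  for (cat_ in DISEASE_CATEGORIES) {
    v <- category_rates(rates, cat_)
    esd[[cat_]] <- if (is.null(k_max)) {
      generalized_esd(v, alpha = esd_alpha)
    } else {
      generalized_esd(v, k_max = k_max, alpha = esd_alpha)
    }
  }
  outliers <- unique(unlist(lapply(esd, `[[`, "outlier_ids"), use.names = FALSE))
  normalized <- setdiff(ids, outliers)
  if (length(normalized) < 3)
    stop_precondition("fewer than 3 hospitals remain after outlier removal")

  # 2-3. normality re-check and tolerance zones over the normalized set
  all_cause <- all_cause_summary(rates)
  rate_of <- function(cat_) {
    if (cat_ == "all_cause") {
      stats::setNames(all_cause$rate, all_cause$hospital_id)[normalized]
    } else {
      category_rates(rates, cat_)[normalized]
    }
  }
  zone_cats <- c(DISEASE_CATEGORIES,
                 if ("all_cause" %in% names(benchmarks)) "all_cause")
  normality <- list()
  warnings <- character(0)
  zones <- list()
  flag_rows <- list()
  for (cat_ in zone_cats) {
    v <- rate_of(cat_)
    normality[[cat_]] <- tryCatch(normality_check(v, alpha = sw_alpha),
                                  codbench_precondition_error = function(e) NULL)
    if (!is.null(normality[[cat_]]) && !normality[[cat_]]$passed) {
      msg <- sprintf("normalized %s rates fail Shapiro-Wilk (p = %.4g) at alpha = %g",
                     cat_, normality[[cat_]]$p_value, sw_alpha)
      warnings <- c(warnings, msg)
      warning(msg, call. = FALSE)
    }
    zones[[cat_]] <- tolerance_zone(benchmarks[[cat_]], sd(v), category = cat_)
    # outside the zone: at or above the ceiling AND strictly above the
    # benchmark, so a zero-width zone (constant rates at benchmark) flags
    # nothing
    flag_rows[[cat_]] <- data.frame(hospital_id = names(v),
                                    category = cat_,
                                    rate = as.vector(v),
                                    outside = as.vector(v) >= zones[[cat_]]$zone_high &
                                      as.vector(v) > zones[[cat_]]$benchmark_rate,
                                    stringsAsFactors = FALSE)
  }
  benchmarks_df <- do.call(rbind, lapply(zones, function(z)
    data.frame(category = z$category, benchmark_rate = z$benchmark_rate,
               sd = z$sd, zone_low = z$zone_low, zone_high = z$zone_high,
               stringsAsFactors = FALSE)))
  rownames(benchmarks_df) <- NULL
  flag_table <- do.call(rbind, flag_rows)
  rownames(flag_table) <- NULL

  # 4. flag on any disease category (all-cause is report-only)
  disease_flags <- flag_table[flag_table$category %in% DISEASE_CATEGORIES, ]
  flagged <- sort(unique(disease_flags$hospital_id[disease_flags$outside]))

  structure(list(outlier_hospitals = outliers,
                 esd = esd,
                 normalized_set = normalized,
                 normality = normality,
                 benchmarks = benchmarks_df,
                 flag_table = flag_table,
                 flagged = flagged,
                 esd_alpha = esd_alpha,
                 sw_alpha = sw_alpha,
                 warnings = warnings),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d hospitals: %d ESD outlier(s), %d flagged of %d normalized\n",
              length(x$normalized_set) + length(x$outlier_hospitals),
              length(x$outlier_hospitals), length(x$flagged),
              length(x$normalized_set)))
  print(transform(x$benchmarks,
                  sd = round(sd, 3),
                  zone_low = round(zone_low, 2),
                  zone_high = round(zone_high, 2)), row.names = FALSE)
  if (length(x$outlier_hospitals))
    cat("outliers:", paste(x$outlier_hospitals, collapse = ", "), "\n")
  if (length(x$flagged))
    cat("flagged: ", paste(x$flagged, collapse = ", "), "\n")
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Tolerance-zone membership counts by region
#'
#' Tabulates, for each region and category, how many normalized hospitals fall
#' within versus outside (at or above `zone_high`) the tolerance zone, the
#' number of that category's ESD outliers in the region, and the number of
#' hospitals excluded from the normalized set (ESD outliers in any category).
#' For every row, `n_within + n_outside + n_excluded` equals the region's
#' hospital total.
#'
#' @param result a [screen_hospitals()] result.
#' @param rates the [hospital_rates()] table the screen was run on (supplies
#'   the region labels).
#' @return data.frame with columns `region`, `category`, `n_within`,
#'   `n_outside`, `n_outliers`, `n_excluded`, `n_hospitals`.
#' @export
count_zone_membership <- function(result, rates) {
  if (!inherits(result, "screen_result"))
    stop_validation("'result' must be a screen_result")
  if (!inherits(rates, "hospital_rates")) rates <- hospital_rates(rates)
  region_of <- rates[!duplicated(rates$hospital_id),
                     c("hospital_id", "region")]
  if (any(is.na(region_of$region) | !nzchar(region_of$region)))
    stop_validation("hospital '%s' has no region label",
                    region_of$hospital_id[is.na(region_of$region) |
                                            !nzchar(region_of$region)][1])
  region <- stats::setNames(region_of$region, region_of$hospital_id)
  rows <- list()
  for (reg in sort(unique(region))) {
    reg_ids <- names(region)[region == reg]
    excluded <- intersect(result$outlier_hospitals, reg_ids)
    for (cat_ in unique(result$flag_table$category)) {
      ft <- result$flag_table
      sub <- ft[ft$category == cat_ & ft$hospital_id %in% reg_ids, ]
      cat_outliers <- if (cat_ %in% names(result$esd))
        intersect(result$esd[[cat_]]$outlier_ids, reg_ids) else character(0)
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, category = cat_,
        n_within = sum(!sub$outside),
        n_outside = sum(sub$outside),
        n_outliers = length(cat_outliers),
        n_excluded = length(excluded),
        n_hospitals = length(reg_ids),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the flagged hospitals contributing the most deaths
#'
#' Among flagged hospitals, picks the `k` with the largest all-cause death
#' counts. Ties at the cut are broken by lexicographically smaller hospital
#' id, so selection is deterministic.
#'
#' @param flagged character vector of flagged hospital ids.
#' @param all_cause_deaths named numeric vector of all-cause death counts
#'   covering at least the flagged hospitals.
#' @param k number to select, `k <= length(flagged)`.
#' @return character vector of `k` hospital ids, in selection order.
#' @examples
#' select_top_contributors(c("A", "B", "C"),
#'                         c(A = 100, B = 300, C = 200), k = 2)  # B, C
#' @export
select_top_contributors <- function(flagged, all_cause_deaths, k) {
  flagged <- as.character(flagged)
  if (k > length(flagged))
    stop_precondition("k = %d exceeds the %d flagged hospitals", k, length(flagged))
  if (k < 0) stop_validation("'k' must be non-negative")
  missing <- setdiff(flagged, names(all_cause_deaths))
  if (length(missing))
    stop_validation("no death count for flagged hospital '%s'", missing[1])
  d <- all_cause_deaths[flagged]
  ord <- order(-as.numeric(d), flagged)
  flagged[ord][seq_len(k)]
}
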