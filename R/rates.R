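# Cause-specific inpatient death rates and benchmark tolerance zones.

#' Cause-specific inpatient death rate
#'
#' Deaths from a cause among inpatients hospitalized with a diagnosis of that
#' disease, per 100 hospitalizations: `100 * deaths / hospitalizations`,
#' unrounded.
#'
#' @param deaths non-negative integer vector of deaths.
#' @param hospitalizations positive integer vector of hospitalizations with
#'   the diagnosis.
#' @return numeric vector of rates (percent, in `[0, 100]`).
#' @examples
#' inpatient_death_rate(5, 250)  # 2
#' @export
inpatient_death_rate <- function(deaths, hospitalizations) {
  if (length(deaths) != length(hospitalizations))
    stop_validation("'deaths' and 'hospitalizations' must have equal length")
  if (any(is.na(deaths)) || any(is.na(hospitalizations)))
    stop_validation("counts must not contain NA")
  if (any(hospitalizations <= 0))
    stop_validation("hospitalizations must be positive (zero denominator)")
  if (any(deaths < 0))
    stop_validation("deaths must be non-negative")
  if (any(deaths > hospitalizations))
    stop_validation("deaths exceed hospitalizations (%s > %s)",
                    deaths[deaths > hospitalizations][1],
                    hospitalizations[deaths > hospitalizations][1])
  100 * deaths / hospitalizations
}

#' National benchmark inpatient death rates
#'
#' Packaged default benchmarks (percent): CDC estimates of 2010 U.S. inpatient
#' hospital death rates for heart disease (3.5), cancer (4.4), renal disease
#' (3.1), and all-cause death (2.0). Benchmarks are always injected, never
#' computed from the screened cohort.
#'
#' @return named numeric vector with elements `heart`, `cancer`, `renal`,
#'   `all_cause`.
#' @export
default_benchmarks <- function() {
  c(heart = 3.5, cancer = 4.4, renal = 3.1, all_cause = 2.0)
}

#' Benchmark tolerance zone
#'
#' Builds the benchmark +/- 2 SD tolerance zone used to flag hospitals, where
#' the SD is that of the normalized (post-outlier-removal) hospital rate set.
#' Only the upper bound flags: hospitals at or above `zone_high` are outside
#' the zone; `zone_low` is computed for reporting symmetry.
#'
#' @param benchmark_rate benchmark rate (percent).
#' @param sd non-negative standard deviation of the normalized hospital rates
#'   (percent).
#' @param category optional category label carried in the result.
#' @return object of class `benchmark_zone`: list with `category`,
#'   `benchmark_rate`, `sd`, `zone_low`, `zone_high`.
#' @examples
#' tolerance_zone(3.5, 1.2)$zone_high  # 5.9
#' @export
tolerance_zone <- function(benchmark_rate, sd, category = NA_character_) {
  if (!is.numeric(benchmark_rate) || length(benchmark_rate) != 1L)
    stop_validation("'benchmark_rate' must be a single number")
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop_validation("'sd' must be a single non-negative number")
  structure(list(category = category,
                 benchmark_rate = benchmark_rate,
                 sd = sd,
                 zone_low = benchmark_rate - 2 * sd,
                 zone_high = benchmark_rate + 2 * sd),
            class = "benchmark_zone")
}

#' @export
print.benchmark_zone <- function(x, ...) {
  cat(sprintf("<benchmark_zone>%s benchmark %.2f, sd %.3f, zone [%.2f, %.2f]\n",
              if (is.na(x$category)) "" else paste0(" ", x$category),
              x$benchmark_rate, x$sd, x$zone_low, x$zone_high))
  invisible(x)
}

#' Assemble per-hospital, per-category rates
#'
#' Validates a long-format counts table (one row per hospital x category) and
#' attaches the computed death rate. This is the container every screening
#' function consumes; [read_counts_csv()] produces it from disk.
#'
#' @param counts data.frame with columns `hospital_id`, `region`, `category`,
#'   `hospitalizations`, `deaths`.
#' @return the validated data.frame with an added `rate` column (percent),
#'   class `c("hospital_rates", "data.frame")`.
#' @export
hospital_rates <- function(counts) {
  required <- c("hospital_id", "region", "category", "hospitalizations", "deaths")
  missing <- setdiff(required, names(counts))
  if (length(missing))
    stop_validation("counts table is missing column(s): %s",
                    paste(missing, collapse = ", "))
  counts$hospital_id <- as.character(counts$hospital_id)
  counts$region <- as.character(counts$region)
  counts$category <- as.character(counts$category)
  bad_cat <- setdiff(unique(counts$category), cause_categories())
  if (length(bad_cat))
    stop_validation("unknown category '%s' (expected one of %s)",
                    bad_cat[1], paste(cause_categories(), collapse = ", "))
  if (anyDuplicated(counts[c("hospital_id", "category")]))
    stop_validation("duplicated hospital_id x category rows")
  counts$rate <- inpatient_death_rate(counts$deaths, counts$hospitalizations)
  class(counts) <- c("hospital_rates", "data.frame")
  counts
}

# rate vector for one category, named by hospital id
category_rates <- function(rates, category) {
  sub <- rates[rates$category == category, ]
  stats::setNames(sub$rate, sub$hospital_id)
}

# all-cause rate per hospital: total deaths / total hospitalizations, and the
# all-cause death count (the volume measure used to pick top contributors)
all_cause_summary <- function(rates) {
  deaths <- tapply(rates$deaths, rates$hospital_id, sum)
  hosp <- tapply(rates$hospitalizations, rates$hospital_id, sum)
  ids <- names(deaths)
  data.frame(hospital_id = ids,
             all_cause_deaths = as.vector(deaths),
             hospitalizations = as.vector(hosp),
             rate = 100 * as.vector(deaths) / as.vector(hosp),
             stringsAsFactors = FALSE)
}
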