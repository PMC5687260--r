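# Synthetic hospital cohorts with a known cause-transfer misreporting
# mechanism, so every pipeline stage can be validated against ground truth.
#
# Data-generating model, per hospital h and true cause t:
#   hospitalizations H_ht ~ 1 + NegBin(mu_t - 1, size)   (left-truncated at 1)
#   true deaths      D_ht ~ Binomial(H_ht, p_t)
#   certificate cause of each death ~ Categorical(T_h[t, ]), where T_h is a
#   row-stochastic 4x4 transfer matrix (identity at honest hospitals).
# The certificate ICD-10 root is drawn uniformly from the certified
# category's code set; chart review recovers the true cause; chart
# availability is independent Bernoulli. Transfers relabel causes without
# creating or destroying deaths, so all-cause death counts are invariant to
# the transfer matrix by construction.

# representative "other" roots for certificate codes outside the three
# audited categories (pneumonia, COPD, sepsis, dementia, diabetes, liver
# disease, stroke, femur fracture)
OTHER_ICD_ROOTS <- c("J18", "J44", "A41", "G30", "E11", "K70", "I64", "S72")

#' Identity cause-transfer matrix
#'
#' The 4x4 transfer matrix of an honest hospital: every death is certified as
#' its true cause.
#'
#' @return 4x4 identity matrix with [cause_categories()] dimnames.
#' @export
identity_transfer <- function() {
  k <- cause_categories()
  m <- diag(length(k))
  dimnames(m) <- list(true = k, certified = k)
  m
}

#' Simulation configuration
#'
#' Validates and assembles the configuration for [simulate_study()].
#'
#' @param n_hospitals number of hospitals (>= 5).
#' @param region_labels character vector: either one label per hospital or a
#'   set of region names the hospitals are split across evenly (default two
#'   regions `"east_metro"`, `"west_metro"`).
#' @param hosp_mean named numeric vector: mean hospitalizations per category.
#' @param hosp_dispersion negative-binomial size parameter (larger = closer
#'   to Poisson); `Inf` gives (truncated) Poisson counts.
#' @param true_death_prob named numeric vector: per-category true death
#'   probability per hospitalization.
#' @param transfer_matrix 4x4 row-stochastic matrix `T[true, certified]`
#'   applied at misreporting hospitals (rows sum to 1 within 1e-9).
#' @param misreporting_hospitals integer indices (1..n) or hospital ids
#'   (`"H01"`...) of hospitals the transfer applies to; all others use the
#'   identity transfer.
#' @param chart_availability probability a sampled chart is available.
#' @param seed integer seed; the study is fully reproducible from it.
#' @return object of class `sim_config` (a validated list, with
#'   `hospital_ids` and per-hospital `regions` filled in).
#' @export
sim_config <- function(n_hospitals = 30,
                       region_labels = c("east_metro", "west_metro"),
                       hosp_mean = c(heart = 4000, cancer = 2500,
                                     renal = 1200, other = 12000),
                       hosp_dispersion = 30,
                       true_death_prob = c(heart = 0.035, cancer = 0.044,
                                           renal = 0.031, other = 0.0089),
                       transfer_matrix = identity_transfer(),
                       misreporting_hospitals = integer(0),
                       chart_availability = 0.88,
                       seed = 1L) {
  k <- cause_categories()
  if (!is.numeric(n_hospitals) || n_hospitals < 5)
    stop_validation("'n_hospitals' must be at least 5")
  n_hospitals <- as.integer(n_hospitals)
  hospital_ids <- sprintf("H%02d", seq_len(n_hospitals))
  regions <- if (length(region_labels) == n_hospitals) {
    as.character(region_labels)
  } else {
    # split hospitals across the named regions in contiguous blocks
    rep(as.character(region_labels),
        each = ceiling(n_hospitals / length(region_labels)))[seq_len(n_hospitals)]
  }
  if (length(regions) != n_hospitals)
    stop_validation("'region_labels' must give one region per hospital")
  for (v in list(hosp_mean, true_death_prob)) {
    if (!all(k %in% names(v)))
      stop_validation("per-category parameters need names %s",
                      paste(k, collapse = ", "))
  }
  if (any(hosp_mean[k] < 1)) stop_validation("'hosp_mean' must be >= 1")
  if (any(true_death_prob[k] < 0 | true_death_prob[k] > 1))
    stop_validation("'true_death_prob' must lie in [0, 1]")
  tm <- as.matrix(transfer_matrix)
  if (!all(dim(tm) == c(4, 4)))
    stop_validation("'transfer_matrix' must be 4x4")
  if (is.null(dimnames(tm))) dimnames(tm) <- list(true = k, certified = k)
  tm <- tm[k, k]
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    stop_validation("'transfer_matrix' rows must be non-negative and sum to 1")
  if (is.numeric(misreporting_hospitals)) {
    if (any(misreporting_hospitals < 1 | misreporting_hospitals > n_hospitals))
      stop_validation("'misreporting_hospitals' indices out of range")
    misreporting <- hospital_ids[as.integer(misreporting_hospitals)]
  } else {
    misreporting <- as.character(misreporting_hospitals)
    if (!all(misreporting %in% hospital_ids))
      stop_validation("unknown misreporting hospital id")
  }
  if (is.na(chart_availability) || chart_availability < 0 || chart_availability > 1)
    stop_validation("'chart_availability' must be in [0, 1]")
  structure(list(n_hospitals = n_hospitals,
                 hospital_ids = hospital_ids,
                 regions = regions,
                 hosp_mean = hosp_mean[k],
                 hosp_dispersion = hosp_dispersion,
                 true_death_prob = true_death_prob[k],
                 transfer_matrix = tm,
                 misreporting_hospitals = misreporting,
                 chart_availability = chart_availability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d hospitals in %d region(s), %d misreporting, availability %.2f, seed %d\n",
              x$n_hospitals, length(unique(x$regions)),
              length(x$misreporting_hospitals), x$chart_availability, x$seed))
  invisible(x)
}

# draw truncated-at-1 hospitalization counts
draw_hospitalizations <- function(n, mu, size) {
  if (is.infinite(size)) 1L + stats::rpois(n, mu - 1)
  else 1L + rnbinom(n, size = size, mu = mu - 1)
}

#' Simulate a synthetic hospital study
#'
#' Generates hospitalization and death counts, individual death records with
#' certificate codes produced by the cause-transfer mechanism, chart-review
#' gold labels (the true cause), and chart availability flags. Byte-identical
#' output is guaranteed for identical configurations: all randomness flows
#' from `config$seed`. Hospitalization and true-death counts are drawn before
#' any certificate labelling, so they are invariant to the transfer matrix at
#' a fixed seed.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_study`: list with
#'   `counts` (hospital x category: `hospitalizations`, `true_deaths`,
#'   `certified_deaths`), `deaths` (one row per death: `hospital_id`,
#'   `death_id`, `true_category`, `dc_category`, `dc_icd10`,
#'   `chart_category`, `available`), `config`, and `truth`
#'   (`misreporting_hospitals`, `transfer_matrix`).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_validation("'config' must be a sim_config")
  k <- cause_categories()
  n <- config$n_hospitals
  codes <- default_codesets()
  roots <- list(heart = codes$heart$prefixes, cancer = codes$cancer$prefixes,
                renal = codes$renal$prefixes, other = OTHER_ICD_ROOTS)
  with_seed(config$seed, {
    # counts first: invariant to the transfer matrix at fixed seed
    H <- sapply(k, function(cat_)
      draw_hospitalizations(n, config$hosp_mean[[cat_]], config$hosp_dispersion))
    D <- sapply(k, function(cat_)
      rbinom(n, H[, cat_], config$true_death_prob[[cat_]]))
    if (n == 1) { H <- matrix(H, 1); D <- matrix(D, 1)
                  colnames(H) <- colnames(D) <- k }

    death_rows <- vector("list", n * length(k))
    certified <- matrix(0L, n, length(k), dimnames = list(NULL, k))
    idx <- 0L
    for (h in seq_len(n)) {
      hid <- config$hospital_ids[h]
      tm <- if (hid %in% config$misreporting_hospitals)
        config$transfer_matrix else identity_transfer()
      serial <- 0L
      for (t in k) {
        d <- D[h, t]
        idx <- idx + 1L
        if (d == 0) next
        n_to <- as.vector(rmultinom(1, d, tm[t, ]))
        dc <- rep(k, n_to)
        icd <- character(length(dc))
        for (cc in k[n_to > 0]) {
          pool <- roots[[cc]]
          icd[dc == cc] <- pool[sample.int(length(pool), sum(dc == cc),
                                           replace = TRUE)]
        }
        certified[h, ] <- certified[h, ] + n_to
        death_rows[[idx]] <- data.frame(
          hospital_id = hid,
          death_id = sprintf("%s-D%05d", hid, serial + seq_along(dc)),
          true_category = t,
          dc_category = dc,
          dc_icd10 = icd,
          chart_category = t,
          stringsAsFactors = FALSE)
        serial <- serial + length(dc)
      }
    }
    deaths <- do.call(rbind, death_rows[!vapply(death_rows, is.null, logical(1))])
    rownames(deaths) <- NULL
    deaths$available <- runif(nrow(deaths)) < config$chart_availability

    counts <- data.frame(
      hospital_id = rep(config$hospital_ids, times = length(k)),
      region = rep(config$regions, times = length(k)),
      category = rep(k, each = n),
      hospitalizations = as.vector(H),
      true_deaths = as.vector(D),
      certified_deaths = as.vector(certified),
      stringsAsFactors = FALSE)
    counts <- counts[order(counts$hospital_id, match(counts$category, k)), ]
    rownames(counts) <- NULL

    structure(list(counts = counts, deaths = deaths, config = config,
                   truth = list(misreporting_hospitals = config$misreporting_hospitals,
                                transfer_matrix = config$transfer_matrix)),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d hospitals, %d deaths (%d misreporting hospital(s)), seed %d\n",
              x$config$n_hospitals, nrow(x$deaths),
              length(x$truth$misreporting_hospitals), x$config$seed))
  invisible(x)
}

#' Certificate-based rates table of a synthetic study
#'
#' Converts a [simulate_study()] result into the [hospital_rates()] table the
#' screening stage consumes: deaths counted by *certified* category (what a
#' vital-statistics office would observe) over that category's
#' hospitalizations.
#'
#' @param study a `synthetic_study`.
#' @return a [hospital_rates()] table.
#' @export
certified_rates <- function(study) {
  if (!inherits(study, "synthetic_study"))
    stop_validation("'study' must be a synthetic_study")
  counts <- study$counts
  hospital_rates(data.frame(hospital_id = counts$hospital_id,
                            region = counts$region,
                            category = counts$category,
                            hospitalizations = counts$hospitalizations,
                            deaths = counts$certified_deaths,
                            stringsAsFactors = FALSE))
}

# exact E[1/H] for H = 1 + NegBin(size, mu - 1)
expected_inverse_hosp <- function(mu, size) {
  if (is.infinite(size)) {
    kmax <- stats::qpois(1 - 1e-13, mu - 1)
    return(sum(stats::dpois(0:kmax, mu - 1) / (1 + 0:kmax)))
  }
  kmax <- qnbinom(1 - 1e-13, size = size, mu = mu - 1)
  sum(dnbinom(0:kmax, size = size, mu = mu - 1) / (1 + 0:kmax))
}

#' Expected certificate-based death rate
#'
#' Closed-form expectation of the certificate-based rate produced by
#' [simulate_study()] for one hospital and certified category c:
#' `100 * (p_c T[c,c] + sum_{t != c} p_t T[t,c] E[H_t] E[1/H_c])`,
#' using the exact `E[1/H]` of the truncated negative-binomial
#' hospitalization law (the cross-category terms are ratios of independent
#' counts, so `E[H_t / H_c] = E[H_t] E[1/H_c]`). Serves as the simulation
#' oracle.
#'
#' @param config a [sim_config()].
#' @param hospital hospital id (e.g. `"H01"`) or index.
#' @param category certified category.
#' @return expected rate (percent).
#' @export
expected_certified_rate <- function(config, hospital, category) {
  if (!inherits(config, "sim_config"))
    stop_validation("'config' must be a sim_config")
  category <- match.arg(category, cause_categories())
  if (is.numeric(hospital)) hospital <- config$hospital_ids[hospital]
  if (!hospital %in% config$hospital_ids)
    stop_validation("unknown hospital '%s'", hospital)
  tm <- if (hospital %in% config$misreporting_hospitals)
    config$transfer_matrix else identity_transfer()
  p <- config$true_death_prob
  mu <- config$hosp_mean
  k <- cause_categories()
  einv <- expected_inverse_hosp(mu[[category]], config$hosp_dispersion)
  rate <- p[[category]] * tm[category, category]
  for (t in setdiff(k, category))
    rate <- rate + p[[t]] * tm[t, category] * mu[[t]] * einv
  100 * rate
}

#' Packaged benchmark-calibrated scenario
#'
#' A ready-made study scenario calibrated to the national benchmark rates:
#' 30 hospitals split across two metro regions, baseline true death
#' probabilities 0.035 (heart), 0.044 (cancer), 0.031 (renal) and 0.0089
#' (other; chosen so the expected all-cause rate is 2.0), mean per-category
#' hospitalizations 4000/2500/1200/12000 (negative binomial, size 30), and
#' eight misreporting hospitals (four per region) whose certificates transfer
#' 60% of cancer deaths to heart disease and 8% of other deaths to renal
#' disease — the mechanism by which cancer is underreported while heart and
#' renal rates inflate, leaving all-cause rates untouched. Chart availability
#' is 0.88.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
make_paper_like_scenario <- function(seed = 1L) {
  k <- cause_categories()
  tm <- identity_transfer()
  tm["cancer", "heart"] <- 0.6
  tm["cancer", "cancer"] <- 0.4
  tm["other", "renal"] <- 0.08
  tm["other", "other"] <- 0.92
  sim_config(
    n_hospitals = 30,
    region_labels = c("east_metro", "west_metro"),
    hosp_mean = c(heart = 4000, cancer = 2500, renal = 1200, other = 12000),
    hosp_dispersion = 30,
    true_death_prob = c(heart = 0.035, cancer = 0.044, renal = 0.031,
                        other = 0.0089),
    transfer_matrix = tm,
    misreporting_hospitals = c("H01", "H04", "H08", "H12",
                               "H17", "H20", "H24", "H28"),
    chart_availability = 0.88,
    seed = seed)
}
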