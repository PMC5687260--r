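# CSV readers/writers and configuration files.
#
# CSV dialect: comma-separated, UTF-8, header row required, "." decimal
# separator. ICD ranges in config accept en dash or hyphen; outputs always
# use the ASCII hyphen.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_validation("%s: missing column(s) %s", path,
                    paste(missing, collapse = ", "))
  df
}

#' Read a hospital counts CSV
#'
#' Long format, one row per hospital x category, header
#' `hospital_id,region,category,hospitalizations,deaths`. Rows are validated
#' individually; errors name the offending file line (header is line 1).
#'
#' @param path CSV path.
#' @return a [hospital_rates()] table (rates computed on load).
#' @export
read_counts_csv <- function(path) {
  df <- read_csv_checked(path, c("hospital_id", "region", "category",
                                 "hospitalizations", "deaths"))
  line <- seq_len(nrow(df)) + 1L  # header occupies line 1
  bad <- which(!is.finite(df$hospitalizations) | df$hospitalizations <= 0)
  if (length(bad))
    stop_validation("%s line %d: hospitalizations must be a positive count",
                    path, line[bad[1]])
  bad <- which(!is.finite(df$deaths) | df$deaths < 0)
  if (length(bad))
    stop_validation("%s line %d: deaths must be a non-negative count",
                    path, line[bad[1]])
  bad <- which(df$deaths > df$hospitalizations)
  if (length(bad))
    stop_validation("%s line %d: deaths (%g) exceed hospitalizations (%g)",
                    path, line[bad[1]], df$deaths[bad[1]],
                    df$hospitalizations[bad[1]])
  hospital_rates(df)
}

#' Write a hospital counts CSV
#'
#' Inverse of [read_counts_csv()]; the computed `rate` column is dropped so
#' the round trip is lossless on the integer fields.
#'
#' @param rates a [hospital_rates()] table (or compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(rates, path) {
  cols <- c("hospital_id", "region", "category", "hospitalizations", "deaths")
  write.csv(as.data.frame(rates)[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a death-records CSV
#'
#' Header `hospital_id,death_id,dc_icd10` with optional `chart_category`
#' (required for the concordance stage) and `available` (logical chart
#' availability flags).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_death_records_csv <- function(path) {
  df <- read_csv_checked(path, c("hospital_id", "death_id", "dc_icd10"))
  if (anyDuplicated(df$death_id))
    stop_validation("%s: duplicated death_id '%s'", path,
                    df$death_id[duplicated(df$death_id)][1])
  if ("available" %in% names(df)) df$available <- as.logical(df$available)
  df
}

#' Write a death-records CSV
#'
#' @param deaths death-records data.frame (e.g. `simulate_study()$deaths`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_death_records_csv <- function(deaths, path) {
  write.csv(deaths, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' Reads a [sim_config()] from YAML (default) or JSON (by file extension).
#' The transfer matrix is given as a nested mapping
#' `transfer_matrix: {cancer: {heart: 0.6, cancer: 0.4}, ...}`; omitted rows
#' or entries default to the identity. Scalar fields mirror the
#' [sim_config()] arguments.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  k <- cause_categories()
  tm <- identity_transfer()
  if (!is.null(raw$transfer_matrix)) {
    for (t in names(raw$transfer_matrix)) {
      if (!t %in% k) stop_validation("unknown transfer-matrix row '%s'", t)
      row <- unlist(raw$transfer_matrix[[t]])
      if (!all(names(row) %in% k))
        stop_validation("unknown transfer-matrix column in row '%s'", t)
      tm[t, ] <- 0
      tm[t, names(row)] <- as.numeric(row)
    }
  }
  args <- list(transfer_matrix = tm)
  for (f in c("n_hospitals", "region_labels", "hosp_dispersion",
              "misreporting_hospitals", "chart_availability", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  for (f in c("hosp_mean", "true_death_prob")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, args)
}

#' Write a simulation configuration file
#'
#' Serialises a [sim_config()] to YAML or JSON (by extension) in the format
#' [read_sim_config()] reads; the round trip preserves the configuration,
#' including row-stochasticity of the transfer matrix.
#'
#' @param config a [sim_config()].
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  if (!inherits(config, "sim_config"))
    stop_validation("'config' must be a sim_config")
  k <- cause_categories()
  tm <- lapply(stats::setNames(k, k), function(t)
    as.list(config$transfer_matrix[t, ]))
  out <- list(n_hospitals = config$n_hospitals,
              region_labels = config$regions,
              hosp_mean = as.list(config$hosp_mean),
              hosp_dispersion = config$hosp_dispersion,
              true_death_prob = as.list(config$true_death_prob),
              transfer_matrix = tm,
              misreporting_hospitals = config$misreporting_hospitals,
              chart_availability = config$chart_availability,
              seed = config$seed)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
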