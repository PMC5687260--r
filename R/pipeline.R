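# End-to-end pipeline: simulate -> screen -> sample -> concordance, with a
# reproducible run manifest.

PIPELINE_STAGES <- c("simulate", "screen", "sample", "concordance")

#' Pipeline configuration
#'
#' Bundles every tunable of [run_pipeline()] with its default. Chart-review
#' sample sizes come from [chart_sample_size()] unless `sample_size` is set.
#'
#' @param scenario a [sim_config()] for the simulate stage (default
#'   [make_paper_like_scenario()] at `seed`).
#' @param benchmarks named benchmark rates ([default_benchmarks()]).
#' @param esd_alpha,esd_k_max,sw_alpha screening parameters
#'   (see [screen_hospitals()]).
#' @param top_k flagged hospitals selected by death volume; capped at the
#'   number flagged (default 3).
#' @param chart_p0,chart_p_alt,chart_alpha,chart_power sample-size
#'   parameters (see [chart_sample_size()]).
#' @param sample_size fixed per-hospital sample size overriding the
#'   power-based computation (`NULL` = compute).
#' @param availability global chart-availability rate used when death records
#'   carry no `available` flags.
#' @param study_hospitals optional explicit study set, for sample/concordance
#'   runs without a screen stage.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL,
                            benchmarks = default_benchmarks(),
                            esd_alpha = 0.1, esd_k_max = NULL,
                            sw_alpha = 0.05,
                            top_k = 3,
                            chart_p0 = 0.05, chart_p_alt = 0.20,
                            chart_alpha = 0.05, chart_power = 0.80,
                            sample_size = NULL,
                            availability = 0.88,
                            study_hospitals = NULL,
                            seed = 1L) {
  if (is.null(scenario)) scenario <- make_paper_like_scenario(seed)
  structure(list(scenario = scenario, benchmarks = benchmarks,
                 esd_alpha = esd_alpha, esd_k_max = esd_k_max,
                 sw_alpha = sw_alpha, top_k = top_k,
                 chart_p0 = chart_p0, chart_p_alt = chart_p_alt,
                 chart_alpha = chart_alpha, chart_power = chart_power,
                 sample_size = sample_size, availability = availability,
                 study_hospitals = study_hospitals,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

screen_result_as_list <- function(screen, selected, study_hospitals) {
  list(outlier_hospitals = screen$outlier_hospitals,
       normalized_set = screen$normalized_set,
       flagged = screen$flagged,
       selected_contributors = selected,
       study_hospitals = study_hospitals,
       benchmarks = screen$benchmarks,
       esd = lapply(screen$esd, function(e)
         list(tested_k = e$tested_k, statistics = e$statistics,
              critical_values = e$critical_values,
              n_outliers = e$n_outliers, outlier_ids = e$outlier_ids,
              alpha = e$alpha)),
       normality = lapply(screen$normality, function(nr)
         if (is.null(nr)) NULL
         else list(W = nr$W, p_value = nr$p_value, passed = nr$passed)),
       warnings = screen$warnings)
}

#' Run the audit pipeline
#'
#' Executes the requested stages in order — simulate, screen, sample,
#' concordance — writing each stage's outputs to `out_dir` before the next
#' begins, and finishing with a run manifest (`manifest.json`) holding the
#' configuration snapshot, derived seeds, output checksums, stage timings and
#' any warnings. A rerun with the same configuration reproduces every output
#' byte-identically.
#'
#' Stage inputs: without `"simulate"`, supply `counts` (for `"screen"`) and
#' `deaths` (for `"sample"`/`"concordance"`) as data.frames or CSV paths.
#' Without `"screen"`, `config$study_hospitals` must name the hospitals to
#' sample. Death records with an `available` column use those flags;
#' otherwise availability is Bernoulli at `config$availability`.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param stages subset of `c("simulate", "screen", "sample", "concordance")`.
#' @param counts optional [hospital_rates()] table or counts CSV path.
#' @param deaths optional death-records data.frame or CSV path.
#' @return invisibly, a list with the stage objects (`study`, `rates`,
#'   `screen`, `selected`, `study_hospitals`, `plans`, `reviewed`, `pairs`,
#'   `concordance`, `directions`) and `manifest`.
#' @export
run_pipeline <- function(out_dir,
                         config = pipeline_config(),
                         stages = PIPELINE_STAGES,
                         counts = NULL, deaths = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (!inherits(config, "pipeline_config"))
    stop_validation("'config' must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  res <- list()
  manifest <- list(package = "codbench",
                   version = as.character(utils::packageVersion("codbench")),
                   stages = stages,
                   seed = config$seed,
                   config = list(
                     benchmarks = as.list(config$benchmarks),
                     esd_alpha = config$esd_alpha,
                     esd_k_max = config$esd_k_max,
                     sw_alpha = config$sw_alpha,
                     top_k = config$top_k,
                     chart = list(p0 = config$chart_p0, p_alt = config$chart_p_alt,
                                  alpha = config$chart_alpha,
                                  power = config$chart_power),
                     sample_size = config$sample_size,
                     availability = config$availability),
                   seeds = list(), timings = list(), warnings = character(0),
                   outputs = list())
  written <- character(0)
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- stage
      manifest$error <<- conditionMessage(e)
      write_manifest(manifest, written, out_dir)
      stop(e)
    })
    manifest$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  if ("simulate" %in% stages) {
    res$study <- timed("simulate", simulate_study(config$scenario))
    counts <- certified_rates(res$study)
    deaths <- res$study$deaths
    write_counts_csv(counts, file.path(out_dir, "counts.csv"))
    write_death_records_csv(deaths, file.path(out_dir, "death_records.csv"))
    write_sim_config(config$scenario, file.path(out_dir, "sim_config.yaml"))
    written <- c(written, "counts.csv", "death_records.csv", "sim_config.yaml")
    manifest$seeds$simulate <- config$scenario$seed
  } else {
    if (is.character(counts)) counts <- read_counts_csv(counts)
    if (is.character(deaths)) deaths <- read_death_records_csv(deaths)
  }

  study_hospitals <- config$study_hospitals
  if ("screen" %in% stages) {
    if (is.null(counts))
      stop_validation("the screen stage needs counts (run simulate or supply them)")
    rates <- if (inherits(counts, "hospital_rates")) counts else hospital_rates(counts)
    res$rates <- rates
    res$screen <- timed("screen", screen_hospitals(
      rates, benchmarks = config$benchmarks, k_max = config$esd_k_max,
      esd_alpha = config$esd_alpha, sw_alpha = config$sw_alpha))
    manifest$warnings <- c(manifest$warnings, res$screen$warnings)
    ac <- all_cause_summary(rates)
    volumes <- stats::setNames(ac$all_cause_deaths, ac$hospital_id)
    res$selected <- select_top_contributors(
      res$screen$flagged, volumes, min(config$top_k, length(res$screen$flagged)))
    study_hospitals <- union(res$screen$outlier_hospitals, res$selected)
    jsonlite::write_json(
      screen_result_as_list(res$screen, res$selected, study_hospitals),
      file.path(out_dir, "screen_result.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
    utils::write.csv(count_zone_membership(res$screen, rates),
                     file.path(out_dir, "zone_membership.csv"),
                     row.names = FALSE, quote = FALSE)
    written <- c(written, "screen_result.json", "zone_membership.csv")
  }
  res$study_hospitals <- study_hospitals

  if ("sample" %in% stages) {
    if (is.null(deaths))
      stop_validation("the sample stage needs death records")
    if (is.null(study_hospitals))
      stop_validation("the sample stage needs a study set (run screen or set config$study_hospitals)")
    if (!"dc_category" %in% names(deaths))
      deaths$dc_category <- classify_cause(deaths$dc_icd10)
    n_target <- config$sample_size %||% chart_sample_size(
      config$chart_p0, config$chart_p_alt, config$chart_alpha, config$chart_power)
    res$plans <- timed("sample", {
      plans <- list(); reviewed_ids <- character(0)
      for (i in seq_along(study_hospitals)) {
        hid <- study_hospitals[i]
        eligible <- deaths$death_id[deaths$hospital_id == hid &
                                      deaths$dc_category %in% DISEASE_CATEGORIES]
        n_draw <- min(n_target, length(eligible))
        draw_seed <- derive_seed(config$seed, i)
        drawn <- draw_chart_sample(eligible, n_draw, draw_seed)
        availability <- if ("available" %in% names(deaths)) {
          stats::setNames(deaths$available, deaths$death_id)[drawn]
        } else config$availability
        aa <- apply_availability(drawn, availability,
                                 seed = derive_seed(config$seed, 1000 + i),
                                 hospital_id = hid,
                                 eligible_deaths = length(eligible),
                                 n_target = n_target)
        aa$plan$draw_seed <- draw_seed
        plans[[hid]] <- aa$plan
        reviewed_ids <- c(reviewed_ids, aa$reviewed)
        # the braced block is evaluated in run_pipeline's frame, so these
        # assignments update the pipeline state directly
        manifest$seeds[[paste0("sample_", hid)]] <- draw_seed
      }
      res$reviewed <- reviewed_ids
      do.call(rbind, plans)
    })
    rownames(res$plans) <- NULL
    utils::write.csv(res$plans, file.path(out_dir, "sample_manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    written <- c(written, "sample_manifest.csv")
  }

  if ("concordance" %in% stages) {
    if (is.null(deaths) || is.null(res$reviewed))
      stop_validation("the concordance stage needs death records and a reviewed sample")
    if (!"chart_category" %in% names(deaths))
      stop_validation("death records need a 'chart_category' column for concordance")
    reviewed_records <- deaths[deaths$death_id %in% res$reviewed, ]
    res$pairs <- timed("concordance", build_pairs(reviewed_records))
    res$concordance <- concordance_table(res$pairs)
    res$directions <- cause_direction_report(res$pairs)
    utils::write.csv(res$concordance,
                     file.path(out_dir, "concordance_table.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$directions, file.path(out_dir, "cause_direction.csv"),
                     row.names = FALSE, quote = FALSE)
    written <- c(written, "concordance_table.csv", "cause_direction.csv")
  }

  manifest <- write_manifest(manifest, written, out_dir)
  res$manifest <- manifest
  invisible(res)
}

write_manifest <- function(manifest, written, out_dir) {
  paths <- file.path(out_dir, written)
  sums <- tools::md5sum(paths)
  manifest$outputs <- stats::setNames(as.list(unname(sums)), written)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest
}
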