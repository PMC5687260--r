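# One full audit replicate on the packaged scenario: simulate, screen
# (ESD cap at the implanted outlier count), chart-sample the study hospitals,
# and test reporting directions on the reviewed pairs.
audit_replicate <- function(seed, n_target = 27L) {
  cfg <- make_paper_like_scenario(seed)
  st <- simulate_study(cfg)
  rates <- certified_rates(st)
  scr <- suppressWarnings(screen_hospitals(rates, k_max = 8))
  ac <- tapply(rates$deaths, rates$hospital_id, sum)
  selected <- select_top_contributors(
    scr$flagged, stats::setNames(as.vector(ac), names(ac)),
    min(3, length(scr$flagged)))
  study <- union(scr$outlier_hospitals, selected)
  reviewed <- character(0)
  for (i in seq_along(study)) {
    eligible <- st$deaths$death_id[st$deaths$hospital_id == study[i] &
                                     st$deaths$dc_category %in%
                                       c("heart", "cancer", "renal")]
    drawn <- draw_chart_sample(eligible, min(n_target, length(eligible)),
                               seed = seed * 1000 + i)
    avail <- stats::setNames(st$deaths$available, st$deaths$death_id)[drawn]
    reviewed <- c(reviewed, drawn[avail])
  }
  pairs <- build_pairs(st$deaths[st$deaths$death_id %in% reviewed, ])
  dir_ <- cause_direction_report(pairs)
  heart <- dir_[dir_$cause == "heart", ]
  cancer <- dir_[dir_$cause == "cancer", ]
  list(
    recovered = all(cfg$misreporting_hospitals %in%
                      union(scr$outlier_hospitals, scr$flagged)),
    heart_over_sig = heart$direction == "overreport" && heart$p_value < 0.05,
    cancer_under_sig = cancer$direction == "underreport" && cancer$p_value < 0.05,
    n_pairs = nrow(pairs))
}
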