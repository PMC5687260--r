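# The synthetic cohort generator and its closed-form oracles.

small_cfg <- function(seed = 1, tm = identity_transfer(),
                      misreporting = integer(0), availability = 1.0) {
  sim_config(n_hospitals = 5,
             hosp_mean = c(heart = 300, cancer = 250, renal = 150, other = 700),
             hosp_dispersion = 20,
             true_death_prob = c(heart = 0.035, cancer = 0.044,
                                 renal = 0.031, other = 0.012),
             transfer_matrix = tm,
             misreporting_hospitals = misreporting,
             chart_availability = availability,
             seed = seed)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_hospitals = 4), class = "codbench_validation_error")
  bad_tm <- identity_transfer(); bad_tm["cancer", "heart"] <- 0.5
  expect_error(small_cfg(tm = bad_tm), class = "codbench_validation_error")
  expect_error(small_cfg(availability = 1.5), class = "codbench_validation_error")
  expect_error(sim_config(n_hospitals = 10, misreporting_hospitals = 11),
               class = "codbench_validation_error")
  cfg <- make_paper_like_scenario(3)
  expect_s3_class(cfg, "sim_config")
  expect_true(all(abs(rowSums(cfg$transfer_matrix) - 1) < 1e-9))
})

test_that("identical configurations give byte-identical studies", {
  s1 <- simulate_study(small_cfg(seed = 42))
  s2 <- simulate_study(small_cfg(seed = 42))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$deaths, s2$deaths)
  expect_false(identical(s1$deaths,
                         simulate_study(small_cfg(seed = 43))$deaths))
})

test_that("identity transfer with full availability yields perfect concordance", {
  st <- simulate_study(small_cfg(seed = 9))
  expect_true(all(st$deaths$dc_category == st$deaths$chart_category))
  expect_true(all(st$deaths$available))
  tab <- concordance_table(build_pairs(st$deaths))
  expect_true(all(tab$pct_inaccurate == 0))
})

test_that("certificate codes classify to the certified category", {
  tm <- identity_transfer()
  tm["cancer", ] <- c(0.5, 0.5, 0, 0)
  st <- simulate_study(small_cfg(seed = 14, tm = tm, misreporting = 1:5))
  expect_identical(unname(classify_cause(st$deaths$dc_icd10)),
                   st$deaths$dc_category)
  # per hospital/category, record count equals the true death count
  rec <- table(st$deaths$hospital_id, st$deaths$true_category)
  for (h in rownames(rec)) {
    for (cat_ in colnames(rec)) {
      expect_identical(
        as.integer(rec[h, cat_]),
        st$counts$true_deaths[st$counts$hospital_id == h &
                                st$counts$category == cat_])
    }
  }
})

test_that("certified counts follow the transfer-matrix closed form", {
  # cancer -> heart transfer 0.5 at every hospital; over replicates the mean
  # certified heart count must match true heart + 0.5 * true cancer deaths
  tm <- identity_transfer()
  tm["cancer", ] <- c(0.5, 0.5, 0, 0)
  tot_cert <- tot_expect <- 0
  for (s in 1:500) {
    st <- simulate_study(small_cfg(seed = 10000 + s, tm = tm,
                                   misreporting = 1:5))
    heart_rows <- st$counts$category == "heart"
    cancer_rows <- st$counts$category == "cancer"
    tot_cert <- tot_cert + sum(st$counts$certified_deaths[heart_rows])
    tot_expect <- tot_expect + sum(st$counts$true_deaths[heart_rows]) +
      0.5 * sum(st$counts$true_deaths[cancer_rows])
  }
  expect_lt(abs(tot_cert / tot_expect - 1), 0.02)
})

test_that("expected certified rate reduces to the death probability under identity", {
  cfg <- small_cfg()
  for (cat_ in cause_categories()) {
    expect_equal(expected_certified_rate(cfg, "H01", cat_),
                 100 * cfg$true_death_prob[[cat_]])
  }
})

test_that("expected certified rate increases with the transfer inflow", {
  tm1 <- identity_transfer()
  tm1["cancer", ] <- c(0.25, 0.75, 0, 0)
  tm2 <- identity_transfer()
  tm2["cancer", ] <- c(0.5, 0.5, 0, 0)
  r1 <- expected_certified_rate(small_cfg(tm = tm1, misreporting = 1), 1, "heart")
  r2 <- expected_certified_rate(small_cfg(tm = tm2, misreporting = 1), 1, "heart")
  base <- expected_certified_rate(small_cfg(), 1, "heart")
  expect_gt(r1, base)
  expect_gt(r2, r1)
})

test_that("simulated rates match the closed-form expectation within Monte Carlo error", {
  tm <- identity_transfer()
  tm["cancer", ] <- c(0.5, 0.5, 0, 0)
  tm["other", ] <- c(0, 0, 0.1, 0.9)
  cfg0 <- small_cfg(tm = tm, misreporting = 1:5)
  n_rep <- 500
  rates <- matrix(NA_real_, n_rep, 2)
  for (s in seq_len(n_rep)) {
    st <- simulate_study(small_cfg(seed = 20000 + s, tm = tm,
                                   misreporting = 1:5))
    r <- certified_rates(st)
    rates[s, 1] <- mean(r$rate[r$category == "heart"])
    rates[s, 2] <- mean(r$rate[r$category == "renal"])
  }
  for (j in 1:2) {
    cat_ <- c("heart", "renal")[j]
    expected <- expected_certified_rate(cfg0, 1, cat_)
    se <- sd(rates[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(rates[, j]) - expected), 3 * se)
  }
})

test_that("all-cause deaths are invariant to the transfer matrix at fixed seed", {
  tm <- identity_transfer()
  tm["cancer", ] <- c(0.6, 0.4, 0, 0)
  for (s in c(3, 8, 15)) {
    honest <- simulate_study(small_cfg(seed = s))
    shifted <- simulate_study(small_cfg(seed = s, tm = tm, misreporting = 1:5))
    expect_identical(honest$counts$true_deaths, shifted$counts$true_deaths)
    expect_identical(honest$counts$hospitalizations,
                     shifted$counts$hospitalizations)
    # certified totals move between categories but never in aggregate
    tot_h <- tapply(honest$counts$certified_deaths, honest$counts$hospital_id, sum)
    tot_s <- tapply(shifted$counts$certified_deaths, shifted$counts$hospital_id, sum)
    expect_identical(tot_h, tot_s)
  }
})

test_that("the packaged scenario is benchmark-calibrated", {
  cfg <- make_paper_like_scenario(1)
  expect_identical(cfg$n_hospitals, 30L)
  expect_identical(length(unique(cfg$regions)), 2L)
  expect_identical(length(cfg$misreporting_hospitals), 8L)
  expect_equal(cfg$chart_availability, 0.88)
  # honest hospitals' expected certified rates equal the benchmarks
  for (cat_ in c("heart", "cancer", "renal")) {
    expect_equal(expected_certified_rate(cfg, "H02", cat_),
                 default_benchmarks()[[cat_]], tolerance = 1e-8)
  }
  # expected all-cause rate equals the 2.0 benchmark
  all_cause <- sum(cfg$hosp_mean * cfg$true_death_prob) / sum(cfg$hosp_mean)
  expect_equal(100 * all_cause, 2.0, tolerance = 0.01)
})

test_that("availability parameter reproduces the expected review fraction", {
  reviewed <- drawn <- 0
  for (s in 1:30) {
    cfg <- make_paper_like_scenario(30000 + s)
    st <- simulate_study(cfg)
    reviewed <- reviewed + sum(st$deaths$available)
    drawn <- drawn + nrow(st$deaths)
  }
  expect_lt(abs(reviewed / drawn - 0.88), 0.01)
})

test_that("configuration files round-trip through YAML and JSON", {
  cfg <- make_paper_like_scenario(5)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg.", ext))
    write_sim_config(cfg, path)
    back <- read_sim_config(path)
    expect_equal(back$transfer_matrix, cfg$transfer_matrix)
    expect_true(all(abs(rowSums(back$transfer_matrix) - 1) < 1e-9))
    expect_identical(back$misreporting_hospitals, cfg$misreporting_hospitals)
    expect_equal(back$true_death_prob, cfg$true_death_prob)
    expect_identical(back$seed, cfg$seed)
    unlink(path)
  }
})
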