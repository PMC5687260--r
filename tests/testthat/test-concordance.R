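# Certificate/chart concordance: pairs, tables, McNemar, matched ORs.

make_pairs_df <- function(dc, chart, hospital = "H1") {
  data.frame(hospital_id = hospital,
             death_id = sprintf("%s-%03d", hospital, seq_along(dc)),
             dc_icd10 = dc, chart_category = chart,
             stringsAsFactors = FALSE)
}

test_that("pairs are built from certificate codes, excluding insufficient charts", {
  rec <- make_pairs_df(c("I25.1", "I50.9", "C34.1", "N18.5", "J44.9"),
                       c("heart", "cancer", "cancer", "renal", "insufficient"))
  pairs <- build_pairs(rec)
  expect_identical(nrow(pairs), 4L)
  expect_identical(attr(pairs, "n_insufficient"), 1L)
  expect_identical(pairs$dc_category, c("heart", "heart", "cancer", "renal"))
  concordant <- pairs$dc_category == pairs$chart_category
  expect_identical(concordant, c(TRUE, FALSE, TRUE, TRUE))

  empty <- build_pairs(rec[0, ])
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "n_insufficient"), 0L)
  expect_error(build_pairs(rec[, -3]), class = "codbench_validation_error")
})

test_that("concordance table computes per-hospital and per-cause percentages", {
  # 20 pairs: 10 discordant, 8 of them certified heart, 2 certified renal
  dc <- c(rep("I21", 8), rep("N18", 2), rep("C50", 10))
  chart <- c(rep("cancer", 8), rep("other", 2), rep("cancer", 10))
  tab <- concordance_table(build_pairs(make_pairs_df(dc, chart)))
  h <- tab[tab$hospital_id == "H1", ]
  expect_identical(h$n_reviewed, 20L)
  expect_identical(h$n_inaccurate, 10L)
  expect_identical(h$pct_inaccurate, 50)
  expect_identical(h$pct_heart, 80)
  expect_identical(h$pct_cancer, 0)
  expect_identical(h$pct_renal, 20)

  # all concordant: zero everywhere
  tab0 <- concordance_table(build_pairs(make_pairs_df(rep("I21", 5),
                                                      rep("heart", 5))))
  expect_identical(tab0$pct_inaccurate[1], 0)
  expect_identical(tab0$pct_heart[1], 0)
})

test_that("the mean row is the unweighted mean of per-hospital percentages", {
  dc <- c(rep("I21", 4), rep("C50", 6),   # A: 4/10 inaccurate
          rep("I21", 3), rep("C50", 1))   # B: 3/4 inaccurate
  chart <- c(rep("cancer", 4), rep("cancer", 6),
             rep("cancer", 3), rep("cancer", 1))
  hosp <- c(rep("A", 10), rep("B", 4))
  tab <- concordance_table(build_pairs(make_pairs_df(dc, chart, hosp)))
  mean_row <- tab[tab$hospital_id == "(mean)", ]
  expect_identical(mean_row$pct_inaccurate, pct_mean(c(40, 75)))
  expect_identical(mean_row$pct_heart, 100)
})

test_that("published audit percentages reproduce the published mean row", {
  ref <- audit_reference()
  expect_identical(pct_mean(ref$pct_inaccurate), 45.8)
  expect_identical(pct_mean(ref$pct_heart), 71.9)
  expect_identical(pct_mean(ref$pct_cancer), 3.3)
  expect_identical(pct_mean(ref$pct_renal), 17.3)
})

test_that("discordant counts follow the hand count and the accounting identity", {
  dc <- c(rep("I21", 3), "C50")
  chart <- c(rep("cancer", 3), "heart")
  pairs <- build_pairs(make_pairs_df(dc, chart))
  h <- discordant_counts(pairs, "heart")
  expect_identical(c(h$b, h$c), c(3L, 1L))
  ca <- discordant_counts(pairs, "cancer")
  expect_identical(c(ca$b, ca$c), c(1L, 3L))
  conc <- discordant_counts(build_pairs(make_pairs_df("I21", "heart")), "heart")
  expect_identical(c(conc$b, conc$c), c(0L, 0L))

  # sum of b over all four categories equals total discordant pairs
  for (s in 1:10) {
    set.seed(600 + s)
    k <- cause_categories()
    truth <- sample(k, 50, replace = TRUE)
    cert <- ifelse(runif(50) < 0.4, sample(k, 50, replace = TRUE), truth)
    roots <- c(heart = "I21", cancer = "C50", renal = "N18", other = "J44")
    pairs <- build_pairs(make_pairs_df(unname(roots[cert]), truth))
    total_b <- sum(vapply(k, function(x) discordant_counts(pairs, x)$b,
                          integer(1)))
    expect_identical(total_b, sum(pairs$dc_category != pairs$chart_category))
  }
})

test_that("exact McNemar equals the binomial tail brute force for all b + c <= 25", {
  for (n in 0:25) {
    for (b in 0:n) {
      res <- mcnemar_test(b, n - b, exact = TRUE)
      expect_equal(res$p_value, mcnemar_brute(b, n - b),
                   info = sprintf("b=%d c=%d", b, n - b))
    }
  }
})

test_that("McNemar closed forms match hand computation", {
  expect_identical(mcnemar_test(5, 5)$p_value, 1)
  res <- mcnemar_test(10, 2)
  expect_equal(res$p_value, 158 / 4096)
  expect_equal(res$statistic, 64 / 12)
  asym <- mcnemar_test(10, 2, exact = FALSE)
  expect_equal(asym$statistic, 64 / 12)
  expect_equal(asym$p_value, pchisq(64 / 12, 1, lower.tail = FALSE))
  expect_error(mcnemar_test(0, 0, exact = FALSE),
               class = "codbench_precondition_error")
})

test_that("the asymptotic test converges to the exact test as totals grow", {
  # worst-case |exact - asymptotic| over all splits of b + c shrinks with the
  # discordant total and is inside 0.02 by n = 2000; mid-range p-values at
  # small n differ by up to ~0.14 (binomial discreteness), which is why the
  # exact test is the default
  worst <- vapply(c(30, 100, 500, 2000), function(n) {
    max(vapply(0:n, function(b) {
      abs(mcnemar_test(b, n - b)$p_value -
            mcnemar_test(b, n - b, exact = FALSE)$p_value)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(worst) < 0))
  expect_lt(worst[4], 0.02)
  # in the decision-relevant tail (exact p <= 0.1) agreement is already close
  # at chart-review scale
  for (n in c(30, 60, 120)) {
    for (b in 0:n) {
      pe <- mcnemar_test(b, n - b)$p_value
      if (pe > 0.1) next
      pa <- mcnemar_test(b, n - b, exact = FALSE)$p_value
      expect_lt(abs(pe - pa), 0.05)
    }
  }
})

test_that("matched odds ratios follow b/c with coherent intervals", {
  or <- matched_odds_ratio(10, 2)
  expect_identical(or$or, 5)
  expect_true(or$ci_low <= 5 && 5 <= or$ci_high)
  expect_identical(matched_odds_ratio(7, 7)$or, 1)
  expect_identical(matched_odds_ratio(12, 0, correction = TRUE)$or, 25)
  expect_error(matched_odds_ratio(12, 0), class = "codbench_precondition_error")
  expect_error(matched_odds_ratio(0, 0, correction = TRUE),
               class = "codbench_precondition_error")
  # swapping b and c inverts the OR exactly
  for (bc in list(c(10, 2), c(3, 7), c(1, 19), c(8, 8))) {
    expect_equal(matched_odds_ratio(bc[1], bc[2])$or *
                   matched_odds_ratio(bc[2], bc[1])$or, 1)
  }
  # log-normal interval also brackets the point estimate
  ln <- matched_odds_ratio(10, 2, method = "lognormal")
  expect_equal(ln$or, 5)
  expect_true(ln$ci_low <= 5 && 5 <= ln$ci_high)
  expect_equal(ln$ci_high,
               exp(log(5) + qnorm(0.975) * sqrt(1 / 10 + 1 / 2)))
})

test_that("direction report labels over/under-reporting and respects symmetry", {
  dc <- c(rep("I21", 9), rep("C50", 2), rep("N18", 4))
  chart <- c(rep("cancer", 9), rep("heart", 2), rep("renal", 4))
  pairs <- build_pairs(make_pairs_df(dc, chart))
  rep_ <- cause_direction_report(pairs)
  heart <- rep_[rep_$cause == "heart", ]
  cancer <- rep_[rep_$cause == "cancer", ]
  renal <- rep_[rep_$cause == "renal", ]
  expect_identical(heart$direction, "overreport")
  expect_identical(cancer$direction, "underreport")
  expect_identical(renal$direction, "none")

  # swapping certificate and chart flips directions and inverts ORs
  swapped <- pairs
  roots <- c(heart = "I21", cancer = "C50", renal = "N18", other = "J44")
  swapped$dc_icd10 <- unname(roots[pairs$chart_category])
  swapped$chart_category <- pairs$dc_category
  rep_sw <- cause_direction_report(build_pairs(swapped))
  expect_identical(rep_sw$direction[rep_sw$cause == "heart"], "underreport")
  expect_identical(rep_sw$direction[rep_sw$cause == "cancer"], "overreport")
  expect_equal(rep_sw$or[rep_sw$cause == "heart"] *
                 rep_$or[rep_$cause == "heart"], 1)
  expect_equal(rep_sw$b, rep_$c)
})
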