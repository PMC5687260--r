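# Independent oracles used across the suite. Each is written from the
# textbook definition, independently of the package's code paths.

# Two-sided Grubbs test for a single outlier: statistic G = max|x - mean|/s,
# critical value ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with
# t = qt(1 - alpha/(2n), n - 2).
grubbs_oracle <- function(x, alpha = 0.1) {
  n <- length(x)
  dev <- abs(x - mean(x)) / sd(x)
  j <- which.max(dev)
  tq <- qt(1 - alpha / (2 * n), n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  list(index = j, G = dev[j], crit = crit, reject = dev[j] > crit)
}

# Exact two-sided McNemar p as the probability of outcomes at least as
# asymmetric as observed under Binomial(b + c, 1/2).
mcnemar_brute <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- 0:n
  sum(dbinom(k[abs(k - n / 2) >= abs(b - n / 2)], n, 0.5))
}

# Brute-force exact one-sided binomial sample size: scan n upward, find the
# exact critical count at level alpha under p0, accept the first n whose
# power under p_alt reaches the target.
sample_size_brute <- function(p0, p_alt, alpha, power, n_max = 500) {
  for (n in 1:n_max) {
    x_crit <- n + 1
    for (x in 0:n) {
      if (sum(dbinom(x:n, n, p0)) <= alpha) { x_crit <- x; break }
    }
    pw <- if (x_crit > n) 0 else sum(dbinom(x_crit:n, n, p_alt))
    if (pw >= power) return(n)
  }
  NA_integer_
}

# small long-format rates fixture builder
make_counts <- function(ids, regions, heart, cancer, renal,
                        hosp = c(heart = 1000, cancer = 1000, renal = 1000)) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(hospital_id = ids[i], region = regions[i],
               category = c("heart", "cancer", "renal"),
               hospitalizations = as.integer(hosp),
               deaths = as.integer(c(heart[i], cancer[i], renal[i])),
               stringsAsFactors = FALSE)
  }))
}

# cohort of n hospitals whose rates are benchmark plus N(0, sd) noise, with
# chosen hospitals' category rates multiplied by `inflate`
make_rate_cohort <- function(n, seed, sd = 0.3, inflate = NULL,
                             inflate_ids = character(0),
                             inflate_category = "heart") {
  set.seed(seed)
  ids <- sprintf("S%02d", 1:n)
  bm <- default_benchmarks()
  hosp <- 5000L
  counts <- list()
  for (cat_ in c("heart", "cancer", "renal")) {
    rate <- pmax(0.05, rnorm(n, bm[[cat_]], sd))
    if (!is.null(inflate) && cat_ == inflate_category)
      rate[ids %in% inflate_ids] <- rate[ids %in% inflate_ids] * inflate
    counts[[cat_]] <- data.frame(hospital_id = ids, region = "one",
                                 category = cat_, hospitalizations = hosp,
                                 deaths = round(rate / 100 * hosp),
                                 stringsAsFactors = FALSE)
  }
  hospital_rates(do.call(rbind, counts))
}
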