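---
title: "Methods: benchmark screening of cause-of-death reporting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark screening of cause-of-death reporting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codbench)
```

## The audit model

`codbench` formalises a vital-statistics audit that asks: *which hospitals'
certified cause-of-death mix is implausible against a national benchmark,
and when their charts are reviewed, in which direction do their certificates
err?* The pipeline has four stages — rates, screening, chart sampling,
concordance — plus a synthetic data generator that provides ground truth for
all of them.

### Rates

For hospital $h$ and disease category $c$, the cause-specific inpatient
death rate is
$$ r_{hc} = 100 \cdot \frac{\text{deaths}_{hc}}{\text{hospitalizations}_{hc}} \;, $$
a percentage in $[0, 100]$, kept unrounded internally. Categories are
defined by 3-character ICD-10 roots (heart disease I00–I09, I11, I13,
I20–I51; cancer C00–C97; renal disease N00–N07, N17–N19, N25–N27); any other
root is the complement category `other`. Classification deliberately ignores
4th-character detail — the category definitions are all at root level — and
unusual but syntactically valid roots (`U07`, say) map to `other` rather
than erroring, because screening data can contain any code. Rates are raw:
no case-mix adjustment and no small-sample shrinkage, on the assumption that
the cohort has already been restricted to hospitals with a meaningful death
volume.

### Screening

The screen assumes hospital rates within a category are approximately
normal apart from a small number of aberrant hospitals. Three choices that a
terse description of such a procedure leaves open are resolved as follows:

* **Per-category ESD with union.** Rosner's generalized ESD test
  (two-sided, $\alpha = 0.1$) runs separately on each disease category's
  rates; a hospital extreme in *any* category is an outlier. Critical
  values use the standard construction
  $\lambda_i = (n-i)\, t_{p,\nu} / \sqrt{(\nu + t_{p,\nu}^2)(n-i+1)}$ with
  $\nu = n-i-1$ and $p = 1 - \alpha / (2(n-i+1))$, and the declared count is
  the *largest* $i$ with $R_i > \lambda_i$, which keeps the test robust to
  masking provided `k_max` is at least the true outlier count.
* **Per-category SDs.** After removing the outlier union, the tolerance
  zone for category $c$ is $\text{benchmark}_c \pm 2\,\hat\sigma_c$, where
  $\hat\sigma_c$ is the SD of that category's remaining ("normalized")
  rates. A single pooled SD cannot produce the different zone widths the
  per-category benchmarks require.
* **High-side flagging.** Only the ceiling flags: a hospital is *outside*
  the zone when $r_{hc} \ge \text{benchmark}_c + 2\hat\sigma_c$ **and**
  $r_{hc} > \text{benchmark}_c$. The second clause only matters in the
  degenerate zero-width zone ($\hat\sigma_c = 0$, e.g. constant rates),
  where the audit question — "implausibly high" — has no answer and nothing
  should be flagged. `zone_low` is reported for symmetry but never flags.

Benchmarks are always injected (packaged defaults: heart 3.5, cancer 4.4,
renal 3.1, all-cause 2.0 percent, from national inpatient death-rate
estimates), never estimated from the screened cohort — otherwise a uniformly
misreporting cohort would launder itself. The normalized rates are
re-checked with Shapiro–Wilk ($\alpha = 0.05$ by default); a failure is a
recorded warning, not an error, because the zone is still computable — its
"$\pm 2$ SD $\approx$ 95%" interpretation is simply weaker. All-cause rates
get a zone for reporting but neither feed the ESD step nor flag.

`k_max`, the number of outliers the ESD tests for, defaults to
$\max(1, \lfloor 0.2 n \rfloor)$ — a conventional cap. It is the one
screening parameter worth thinking about: the generalized ESD *masks* (under-detects)
when the true outlier count exceeds `k_max`, so an analyst who suspects $m$
aberrant hospitals should set `k_max >= m`. The packaged scenario implants
eight misreporting hospitals among thirty and is therefore screened with
`k_max = 8` in the package's own tests.

Tie-breaks are deterministic everywhere: equal studentized deviations remove
the earlier value in input order; equal death volumes in top-contributor
selection prefer the lexicographically smaller hospital id.

### Chart sampling

Per-hospital sample sizes use exact one-sample binomial power: the smallest
$n$ such that the exact one-sided level-$\alpha$ test of
$H_0\!: p = p_0$ rejects with the requested power under $p = p_1$. Defaults
$p_0 = 0.05$, $p_1 = 0.20$, $\alpha = 0.05$, power $0.80$ give $n = 27$
charts per hospital, a typical clinical-review size. Exact binomial power is
sawtoothed in $n$, so "smallest $n$" is the defined rule rather than an
approximation. The audit this package models reported sizes 18–33 per
hospital without stating its formula; the default is documented as a
defensible choice, not a reconstruction. Sampling is simple random without
replacement per hospital, reproducible from a recorded seed; unavailable
charts are dropped (complete case) and counted.

### Concordance

Each reviewed death contributes a matched pair (certificate category, chart
category); chart reviews with insufficient information are excluded and
counted. For cause $X$, the discordant counts are $b$ (certificate-only:
overreporting) and $c$ (chart-only: underreporting).

* **Exact McNemar** is the default because chart reviews yield small
  discordant counts: $p = \min(1,\, 2\,P(\mathrm{Bin}(b+c, 1/2) \le
  \min(b,c)))$. The asymptotic $\chi^2_1$ statistic $(b-c)^2/(b+c)$ is
  available by flag, without continuity correction. The two agree closely in
  the decision-relevant tail but can differ by $\sim$0.14 at mid-range
  $p$-values when $b + c \approx 30$ (binomial discreteness); the worst-case
  gap falls below 0.02 only for discordant totals in the thousands, which is
  why exact is the default and the test suite checks convergence rather than
  blanket agreement.
* **Matched odds ratios** are conditional, $\mathrm{OR} = b/c$, because the
  data are paired. The exact CI transforms the Clopper–Pearson interval for
  $b/(b+c)$ through $p/(1-p)$; a log-normal CI
  $\exp(\log(b/c) \pm z\sqrt{1/b + 1/c})$ is the alternative. Zero cells
  take an optional $+0.5$ continuity correction for the point estimate; the
  exact CI needs none (its bounds are 0 and $\infty$ there). Unconditional
  2×2 ORs are deliberately not used for inference on paired data.
* **Report table.** Per hospital: the percentage of reviewed certificates
  whose category disagrees with the chart, and — among those inaccurate
  certificates — the percentage certified as each audited cause (so rows sum
  to ≤ 100, the remainder certified `other`; using all reviewed charts as
  the denominator would not reproduce how such audit tables are printed).
  The mean row is the *unweighted* mean of per-hospital percentages.
  Report rounding is decimal half-up to one decimal (`round_half_up()`):
  base R's round-half-even would turn a column mean of exactly 3.25 into
  3.2 where printed audit tables show 3.3. Internal values stay unrounded.

### Regional zone-membership counts

`count_zone_membership()` reports, per region and category: hospitals within
the zone, outside it, that category's ESD outliers, and the hospitals
excluded from the normalized set (outliers in any category). Within and
outside are counted over the normalized set only, so
`n_within + n_outside + n_excluded` equals the region's total — a cleaner
accounting than folding outliers into the outside column, at the cost of not
classifying removed hospitals against a zone their removal helped define.

## The synthetic generator

`simulate_study()` draws, per hospital $h$ and true cause $t$:
hospitalizations $H_{ht} \sim 1 + \mathrm{NB}(\mu_t - 1, \text{size})$
(left-truncated so denominators are never zero; size $\to \infty$ gives
Poisson), true deaths $D_{ht} \sim \mathrm{Bin}(H_{ht}, p_t)$, and each
death's certified cause from the row-stochastic transfer matrix
$T[t, \cdot]$ (identity at honest hospitals). A certificate ICD-10 root is
drawn uniformly from the certified category's code set; the chart review
recovers the true cause; availability is independent Bernoulli. Counts are
drawn before any labelling, so death totals are invariant to $T$ at a fixed
seed — the mechanism moves labels, not deaths, matching the audit logic that
all-cause rates stay near benchmark while the cause mix shifts.

The closed-form oracle `expected_certified_rate()` uses
$E[H_t/H_c] = E[H_t]\,E[1/H_c]$ for $t \neq c$ with $E[1/H_c]$ computed
exactly from the truncated negative-binomial pmf, so simulation checks can
use tight Monte-Carlo tolerances without ratio bias.

`make_paper_like_scenario()` packages the study conditions: 30 hospitals in
two metro regions; mean per-category hospitalizations 4000 (heart), 2500
(cancer), 1200 (renal), 12000 (other) with size 30; true death
probabilities 0.035 / 0.044 / 0.031 matching the benchmark rates, and 0.0089
for `other` so the expected all-cause rate is the 2.0 benchmark; eight
misreporting hospitals (four per region) with cancer→heart transfer 0.6 and
other→renal transfer 0.08; chart availability 0.88. The transfer sizes put a
misreporting hospital's certified heart rate near 5.2% — detectable against
the 3.5 benchmark yet far from caricature.

What the generator does **not** emulate: patient covariates and case mix,
admission-volume trends over time, coding errors other than cause transfer,
informatively missing charts (availability is independent Bernoulli, so the
complete-case concordance estimates are unbiased by construction — real
audits cannot assume that), and between-hospital heterogeneity in the
*true* death probabilities. Passing tests therefore demonstrate that the
pipeline recovers a transfer-style misreporting mechanism under realistic
count noise — not that it is robust to confounded case mix, which raw-rate
benchmarking inherently is not.

## Problem sizes and numerical conventions

The test suite and acceptance script size their simulations as follows: 200
replicates of the 30-hospital scenario for recovery and direction checks,
500 replicates of a 5-hospital configuration for closed-form agreement (3
Monte-Carlo SEs), 100 seeded datasets for the ESD≡Grubbs equivalence, and
exhaustive enumeration of all discordant splits with $b + c \le 25$ for the
exact McNemar oracle. Degenerate inputs are policy, not accidents: constant
data stop the ESD with zero outliers; a constant normalized set yields a
zero-width zone that flags nothing; `b = c = 0` makes the OR undefined
(error) and the exact McNemar $p = 1$; `c = 0` requires the continuity
correction for a finite OR.

## Limitations

Raw-rate screening cannot distinguish misreporting from genuinely high
cause-specific mortality; the chart review exists precisely because the
screen is only a triage. The conditional OR's exact CI is conservative
(Clopper–Pearson); the per-hospital percentages in the report table are
rounded to one decimal before the mean row is computed, matching how printed
audit tables are assembled, which can differ from the unrounded mean by a
tenth. ESD validity rests on approximate normality of honest hospitals'
rates; heavy case-mix heterogeneity would call for risk adjustment upstream
of this package.
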