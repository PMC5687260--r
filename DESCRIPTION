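Package: codbench
Title: Benchmarking Hospital Cause-of-Death Reporting Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing the accuracy of hospital cause-of-death
    reporting against national benchmarks. Computes cause-specific inpatient
    death rates from hospitalization and death counts, screens hospitals with
    Rosner's generalized extreme Studentized deviate (ESD) multi-outlier test
    and a benchmark +/- 2 SD tolerance zone, plans and draws chart-review
    samples sized by exact one-sample binomial power, and summarises
    certificate-versus-chart concordance with McNemar tests and matched-pair
    (conditional) odds ratios. Includes a synthetic cohort generator with a
    configurable cause-transfer misreporting mechanism so every pipeline stage
    can be validated against known truth, and an end-to-end pipeline with a
    reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
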