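Package: sbrtcp
Title: Comparing Biophysical Local-Control Models for Lung SBRT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Linear-quadratic dose conversions (BED, EQD2), five
    parameterized tumor-control-probability models for stereotactic body
    radiotherapy of non-small cell lung cancer, a seeded synthetic cohort
    and plan generator, and a paired model-comparison pipeline that
    produces per-patient local-control predictions, pairwise differences
    against a benchmark model, median/range summaries and Wilcoxon
    signed-rank tests across fraction schemes and dose-normalization
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
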