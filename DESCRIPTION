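Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous-report databases: parsing and deduplication of
    quarterly ASCII tables, primary-suspect case selection, per-term and
    per-organ-class 2x2 contingency tables, four disproportionality
    algorithms (reporting odds ratio, proportional reporting ratio, BCPNN
    information component, and DuMouchel's multi-item gamma-Poisson
    shrinker), serious versus non-serious contingency testing with
    chi-square/Fisher selection, demographic stratification, time-to-onset
    summaries with Weibull shape-parameter modelling, and a synthetic
    report generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
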