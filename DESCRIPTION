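Package: petlifetab
Title: Period Life Tables for Dogs and Cats from Clinical Visit Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds Sullivan-style abridged period life tables for companion
    animals from longitudinal veterinary electronic medical records. Covers
    record cleaning, body condition score harmonisation, breed size-group
    assignment, per-survey-year deceased/survivor cohort construction with
    right-censoring by survivor confirmation, stratified tabulation of
    mid-year population and death counts, the life-table columns m(x), q(x),
    l(x), L(x), T(x), e(x) with a 17+ open terminal interval, and Monte-Carlo
    binomial confidence intervals for life expectancy. Includes a synthetic
    EMR generator with Gompertz-Makeham ground-truth mortality so the whole
    pipeline can be validated against analytic life expectancies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
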