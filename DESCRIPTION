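Package: oravigil
Title: Pharmacovigilance Signal Detection for Oral Adverse Events After
    Vaccination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing spontaneous-reporting (individual case
    safety report, ICSR) databases for oral adverse events following
    COVID-19 vaccination. Implements absolute reporting ratios with
    rare-term trimming, cross-database odds-ratio comparison between a
    single-term (PEI-style) and a multi-term (VAERS-style) database,
    hybrid frequentist plus Bayesian disproportionality screening
    (proportional reporting ratio, reporting odds ratio, and shrinkage
    information component with its IC025 credibility bound), stratified
    subgroup reporting rates with chi-squared or Fisher tests, and
    per-term multivariable logistic regression with Wald intervals.
    Ships a synthetic ICSR database generator with known ground truth,
    a packaged oral-term vocabulary, and reference summary counts from
    the German (PEI, 2020-2023) and United States (VAERS, 2020-2024)
    COVID-19 vaccine surveillance datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
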