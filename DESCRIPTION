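Package: cdkresist
Title: Preclinical Response Calling and CDK4/6-Inhibitor Resistance Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for preclinical drug-response analysis in
    patient-derived xenografts (PDX) and short-term ex vivo cultures.
    Converts caliper measurements into ellipsoid tumor volumes and
    mRECIST-like response calls (CR/PR/SD/PD), summarizes cohorts as
    preclinical response and benefit rates with bootstrap standard errors,
    classifies tumors as CDK4/6-inhibitor resistant from a composite
    p16/pRb/cyclin-E1/cyclin-D1 immunohistochemistry rule with Youden-index
    cutoff optimization and concordance metrics, calls single- and
    biallelic ("double hit") gene inactivation from variant consequences
    and allele-specific copy number, fits exposure-association logistic
    models, normalizes qPCR Ct panels with geNorm reference-gene
    selection, and ships seedable synthetic-data generators emulating
    every input so the whole pipeline is testable without animal, slide
    or controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
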