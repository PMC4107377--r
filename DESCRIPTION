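Package: adgrs
Title: Alzheimer's Genetic Risk Scores and Race-Stratified Dementia Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs probability-scale Alzheimer's disease genetic risk
    scores (AD-GRS) from published per-allele log odds ratios, harmonizes
    genotype dosages from VCF or tabular inputs, and fits race-, age- and
    gender-stratified pooled logistic and linear panel models with
    cluster-robust (sandwich) inference. Includes a calibrated synthetic
    cohort generator emulating a two-race biennial health-and-retirement
    panel, tools for converting odds-ratio effects into absolute
    percentage-point risk differences at covariate profiles, and an
    auditable sample-exclusion cascade.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
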