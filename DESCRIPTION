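Package: heightphewas
Title: Phenome-Wide Association and Mendelian Randomization Analysis of Height
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for phenome-wide association studies (PheWAS) of
    measured adult height and Mendelian-randomization PheWAS (MR-PheWAS) of
    genetically-predicted height from electronic-health-record style data.
    Covers cleaning of longitudinal height and weight measurements, phecode
    case/control assignment from ICD diagnosis events, weighted genetic risk
    score construction with allele harmonisation, two-stage least squares
    instrumental-variable estimation with logistic second stages, Bonferroni
    phenome-wide significance thresholds, inverse-variance fixed-effects
    meta-analysis with Cochran Q heterogeneity, cross-population concordance
    diagnostics, and stratified effect-modification analyses. Includes a
    seeded synthetic-cohort generator with a known truth table so every
    stage is testable without restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
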