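Package: metaboaging
Title: Age- and Diet-Associated Metabolome Remodeling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for untargeted LC-MS feature tables sampled
    across lifespan under two dietary regimens. Implements a detection-based
    metabolite-diversity statistic linked to survivorship, a per-feature
    repeated-measures ANOVA screen for age-associated features with
    error-rate-knee threshold calibration and a plug-in false discovery rate,
    cross-diet trajectory concordance against a re-pairing permutation null,
    complete-linkage trajectory clustering with diet-dependence
    classification, and remodeling-delay estimation. Includes a synthetic
    study generator (planted trajectory classes, detection-limit censoring,
    Gompertz survivorship) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
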