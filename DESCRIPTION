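Package: biovar
Title: Biological Variation and Reliability of Repeated Biomarker
    Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reliability analysis for repeated-measures biomarker studies:
    outlier screening of intra-individual variances (Cochran's C) and
    subject means (Reed's criterion), restricted maximum likelihood
    variance decomposition for crude and covariate-adjusted random
    intercept models, intraclass correlation coefficients with subject
    level bootstrap confidence intervals, lognormal conversion between
    variance components and coefficients of variation, reference change
    values, the index of individuality, the number of repeat measurements
    limiting regression-dilution attenuation, ICC sample-size planning,
    longitudinal shift tests, and the revised Goldberg/Black screen for
    energy-intake misreporting.  Includes a synthetic-cohort generator
    with known variance structure so every stage is testable without
    access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
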