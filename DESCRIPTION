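Package: methclocks
Title: Targeted Bisulfite Sequencing Methylation Quantification and
    Epigenetic Clock Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies DNA methylation from targeted bisulfite amplicon
    sequencing read counts (strand-merged beta calling with read-depth
    thresholding and bisulfite-conversion QC), applies four epigenetic
    estimators (two linear age clocks, a pace-of-aging score and a
    mortality risk score) with mean imputation of missing markers,
    calibrates predictor outputs across technologies by polynomial
    transformation, and computes assay-performance statistics
    (sensitivity, repeatability, accuracy against methylation standards,
    cross-method agreement, age-prediction error). Includes a synthetic
    data generator emulating methylation standard dilution series,
    age-structured blood cohorts, lambda spike-ins and platform bias,
    with truth tables for every generated quantity.
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
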