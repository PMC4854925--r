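Package: epidrift
Title: Age-Related Drift and Erosion Analysis of Array Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for array-based DNA methylation cohorts spanning
    a wide age range: probe filtering and beta/M-value handling for Infinium-style
    matrices, differential methylation between age groups via an empirical-Bayes
    moderated t-test with Benjamini-Hochberg adjustment, epigenomic-substructure
    summaries, chronological-age prediction by cross-validated linear support
    vector regression, consensus clustering of the most variable probes,
    detection of discontinuous (step-like) age-related methylation changes by
    single-split regression trees, quantification of age-related erosion of
    methylation patterning (intra-/inter-methylome variance, spatial correlation
    decay, sample heterogeneity), and gene co-expression connectivity contrasts.
    Includes a synthetic-cohort generator that plants each class of age effect
    with a ground-truth table for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    rpart,
    optparse
Config/testthat/edition: 3
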