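Package: thymentropy
Title: Entropy-Based Quantification of Spatial Histological Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra-case spatial heterogeneity of histomorphological
    features measured on multiple slides per thymectomy specimen. Raw slide-level
    measurements (follicle counts, ordinal atrophy and follicular-hyperplasia
    grades, estimated fat percentages) are discretized into a small number of
    levels, and a per-case, per-feature entropy (in bit) summarises how evenly
    the levels are spread across the measurement points of a case. The package
    provides the slide-level and case-level data model with delimited-text I/O,
    a priori level schemes, the entropy statistics with their theoretical
    maxima, a statistical layer (normality-gated two-group tests, Pearson
    correlations, an explorative linear/logistic model grid against clinical
    endpoints, k-fold cross-validation), a synthetic cohort generator with
    plantable clinical effects, and a one-call pipeline that writes all report
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
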