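Package: metaboselect
Title: Consensus Stability Selection for Metabolomics Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-class biomarker-discovery pipeline for untargeted plasma
    metabolomics: interquartile-range outlier masking and missingness filters,
    multi-seed chained imputation with predictive mean matching, per-metabolite
    confounder residualization, a shadow-feature (Boruta-style) random-forest
    selector wrapped in a seed grid and external 10-fold cross-validation to
    define consensus "selection" and "core" metabolite sets, per-metabolite
    discrimination scores (mean decrease Gini, ROC AUC, Mann-Whitney tests,
    relative group differences), maximum-correlation networks over selected
    metabolites, and hypergeometric pathway over-representation analysis.
    Includes a synthetic-data generator that emulates the study design
    (imbalanced classes, correlated metabolite blocks, body-weight and
    collection-day confounding, abundance-dependent missingness) with ground
    truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    igraph,
    jsonlite,
    data.table,
    fgsea,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    withr
Config/testthat/edition: 3
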