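Package: oplsmark
Title: OPLS-DA Biomarker Discovery for Untargeted Faecal Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a complete biomarker-discovery workflow for untargeted
    LC-MS metabolomics feature tables: pooled-QC relative-standard-deviation and
    missingness filtering, log2 transformation and Pareto scaling, orthogonal
    projections to latent structures discriminant analysis (OPLS-DA) with
    predictive/orthogonal variance decomposition and VIP scores, model
    validation by K-fold cross-validation (Q2), label-permutation testing and
    CV-ANOVA, a multi-stage marker filtration cascade (t-test, jack-knife
    confidence intervals, Benjamini-Hochberg FDR, ROC AUC, VIP ranking, Q-Q
    normality), external-calibration quantification with inverse prediction,
    and a synthetic feature-table generator with planted ground truth for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    knitr,
    yaml
Config/testthat/edition: 3
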