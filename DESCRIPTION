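Package: srmpipe
Title: Two-Stage CSF Tryptic Peptide Biomarker Discovery and SRM Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cerebrospinal fluid (CSF) tryptic peptide
    biomarker studies of parkinsonian disorders. Implements the shotgun-stage
    detection filter and differential screen, a seven-criterion selection of
    candidates for selected reaction monitoring (SRM) assay development,
    SRM relative quantification from transition-level peak areas with
    heavy-isotope-label ratio formation, total-protein normalization and
    pooled-QC batch monitoring, an assay-validation framework (calibration
    linearity and coefficient-of-variation criteria), the nonparametric
    statistical battery (Mann-Whitney, Kruskal-Wallis with Dunn post hoc,
    rank analysis of covariance with an age covariate, Spearman correlation,
    chi-squared, ROC/AUC), and random-forest discrimination models built
    from peptide, biochemical-marker and clinical feature families. A
    synthetic-cohort generator reproduces the statistical structure of such
    studies so every stage runs and is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
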