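Package: polyrisk
Title: Polygenic Risk Scores Combined with Classical Risk Factors in
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of small polygenic risk scores
    (PRS) and their integration with classical epidemiological risk
    factors in retrospective case-control studies of breast cancer.
    Provides a packaged 15-SNP susceptibility panel with published
    iCOGS effect sizes, readers for simple CSV and PLINK .raw genotype
    dialects, a Hardy-Weinberg case-control cohort simulator with a
    logistic disease model, PRS computation with configurable
    missing-dosage policies, control-anchored quantile stratification
    with per-bin odds ratios, logistic regression by iteratively
    reweighted least squares, Hosmer-Lemeshow calibration, DeLong
    confidence intervals for the AUC, sensitivity/specificity, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
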