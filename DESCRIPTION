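Package: mibgndb
Title: Normal Databases and Defect Scoring for Cardiac MIBG SPECT Polar Maps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds stratified normal databases (per-segment mean and
    standard deviation) from cohorts of AHA 17-segment iodine-123
    metaiodobenzylguanidine (MIBG) polar-map uptake profiles, scores
    segmental sympathetic-denervation defects against a normal database or
    by visual percent-count thresholds, computes and standardizes the
    planar heart-to-mediastinum count ratio (HMR), and evaluates the
    markers for heart-failure discrimination (agreement, Bland-Altman
    limits, ROC with DeLong inference, Kruskal-Wallis group contrasts, and
    a combined logistic model). A synthetic-cohort generator emulating
    population- and sex-specific uptake structure and focal versus diffuse
    disease patterns exercises the full pipeline without patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
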