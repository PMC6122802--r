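Package: bcriskaug
Title: Biomarker Augmentation of Breast Cancer Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how a polygenic risk score, percent
    mammographic density, and circulating hormones (testosterone, estrone
    sulfate, prolactin) improve the Gail and Rosner-Colditz breast cancer
    risk models. Provides a seeded synthetic nested case-control cohort
    generator with age/menopause/hormone-therapy matching, polygenic risk
    score construction with log-odds-ratio weights, stochastic regression
    imputation of missing biomarkers on the log scale, age-adjusted
    unconditional logistic model augmentation, age-stratified AUC
    meta-analysis with bootstrap delta-AUC inference, two-category net
    reclassification improvement at an absolute-risk threshold, 10-fold
    cross-validation, and Gail-type 5-year absolute risk projection
    against age-specific composite incidence rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
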