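Package: simscore
Title: Continuous Metabolic Syndrome Scoring with the siMS and siMS Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the siMS score, a cutoff-normalized continuous measure of
    metabolic syndrome severity, and the siMS risk score, its age- and
    family-history-adjusted extension, for individual subjects and tabular
    clinical cohorts. Also provides the sample-specific comparator scores
    classically used to quantify metabolic syndrome (sums of age- and
    sex-adjusted standardized residuals, and principal-component factor
    scores), a dichotomous metabolic syndrome classifier following the 2009
    joint harmonized definition with an IDF-style pediatric variant, a
    validation layer (Pearson correlation tables and ROC/AUC against the
    dichotomous diagnosis), and a seeded generator of synthetic clinical
    cohorts with a latent-severity correlation structure for testing entire
    scoring pipelines without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
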