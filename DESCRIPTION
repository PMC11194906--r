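Package: emrqi
Title: Quantitative Quality Index for Electronic Medical Record Data in
    Machine-Learning Risk Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a weighted three-level index system (4 quality
    dimensions, 11 sub-dimensions, 33 computable indicators) for scoring
    the quality and suitability of electronic medical record (EMR) style
    tabular datasets for machine-learning disease-risk prediction.
    Provides the Delphi consultation reliability statistics (response
    rates, expert authority coefficient, coefficient of variation,
    Kendall's coefficient of concordance), analytic hierarchy process
    (AHP) weight derivation with consistency testing, an indicator
    engine measuring completeness, correctness, operability and
    timeliness of a dataset against a reference schema and modeling
    plan, weighted score rollups and scorecard comparison, a
    score-versus-model-performance association analysis with a
    normality-gated Pearson/Spearman choice, and a seeded synthetic
    ICU-style cohort generator with plantable quality defects for
    end-to-end validation without access to credentialed data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    e1071,
    ranger,
    pROC,
    rlang
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
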