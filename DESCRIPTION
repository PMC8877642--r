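Package: deidverify
Title: Scoring and Surrogate-Model Verification of Masking-Based De-Identification Policies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to verify masking-based de-identification (pseudonymization)
    policies for personal health records. Generates synthetic Korean-population
    medical cohorts from published demographic distributions (family names, decade
    age bands, residential areas, blood types, smoking rate), applies per-field
    masking policies, encodes each policy as integer label codes, and scores it by
    a data-usability digit-product rule plus a deduplication-based confidentiality
    statistic banded into interval scores. Tree-based surrogate regressors
    (decision tree, random forest, and depth-wise and leaf-wise gradient boosting)
    are tuned by grid search with k-fold cross-validation to predict the final
    score from the policy encoding, and the boosted surrogates are interpreted
    with exact double-precision TreeSHAP attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    Rcpp,
    rpart,
    stats,
    tools,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
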