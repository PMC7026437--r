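Package: trdburden
Title: Functional-Burden Scores and Prediction of Treatment-Resistant Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted functional-burden scoring of rare and common genetic
    variants and downstream prediction of treatment-resistant depression
    (TRD). Per-variant burden weights combine a functional score (Eigen,
    CADD or sequence-ontology) with a Beta-density allele-frequency weight;
    scores are aggregated over genes, pathways or the whole exome, adjusted
    for ancestry principal components and recruitment centre, and screened
    with a repeated cross-validated correlation-adjusted t-score (CAT) plus
    local false discovery rate filter. Selected predictors feed
    gradient-boosted models whose performance is evaluated with DeLong
    confidence intervals and paired ROC comparisons, including a z-weighted
    clinical risk score and extreme-percentile analyses of the
    importance-weighted total genetic score. A synthetic-cohort generator
    with planted pathway effects and ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    nnet,
    pROC,
    xgboost,
    jsonlite,
    yaml,
    fgsea,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
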