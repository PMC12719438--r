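Package: microec
Title: Multi-Cohort Vaginal Microbiome Classification of Endometrial Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-cohort 16S vaginal-microbiome analysis
    of endometrial cancer status: Dirichlet-multinomial simulation of
    multi-study count tables with batch effects and covariate structure,
    genus-level CLR feature engineering with prevalence filtering, alpha and
    beta diversity (Shannon, Bray-Curtis, Jaccard, Jensen-Shannon, UniFrac)
    with marginal PERMANOVA, bias-corrected covariate-adjusted differential
    abundance with Holm adjustment, empirical-Bayes batch correction,
    SMOTE-NC rebalancing and chained-equation imputation, early- and
    late-integration ensemble classifiers with leave-one-study-out
    validation, and confusion-matrix metrics with exact binomial confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    randomForest,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phyloseq,
    sva
Config/testthat/edition: 3
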