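Package: DisMISL
Title: Distribution-Based Multiple-Instance Survival Learning for Feature-Bag Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements DeepDisMISL, a distribution-based multiple-instance
    survival learning method for whole-slide-image cohorts represented as bags
    of pre-extracted patch feature vectors. A shared instance scorer maps each
    patch to a scalar score; instances at chosen percentiles of the per-bag
    score distribution (optionally with multi-instance neighborhoods) feed a
    multilayer perceptron head trained with the Cox negative log partial
    likelihood. Includes the standard comparator aggregators (mean pooling,
    max pooling over top instances, top/bottom-instance selection, bag-level
    mean features with penalized Cox), censored-survival evaluation
    (Harrell's concordance index, median-threshold risk stratification,
    Kaplan-Meier curves, log-rank test), k-fold cross-validation with early
    stopping, scenario and neighborhood sweeps, percentile-risk
    interpretation curves, and a synthetic bag-cohort generator with
    quantile-dependent proportional hazards for method validation without
    any real slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    glmnet,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Survival, Classification, StatisticalMethod
RoxygenNote: 7.3.3
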