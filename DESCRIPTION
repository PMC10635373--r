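Package: etioclass
Title: Ensemble Consensus Classification of Ischemic Stroke Etiology from
    Discharge Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the four-level TOAST etiology of acute ischemic stroke
    (large-artery atherosclerosis, cardioembolism, small-vessel disease, other
    determined) from features extracted out of semi-structured discharge-summary
    text. Five probabilistic base learners (multinomial logistic regression,
    support-vector classifier, random forest, gradient-boosted trees, and an
    alternative-probability support-vector variant) are combined with four
    renormalized summary-statistic ensembles (mean, median, maximum, minimum)
    into a nine-member consensus voting meta-classifier. A certainty heuristic
    based on quartiles of consensus support reclassifies cryptogenic strokes or
    abstains ("persistently cryptogenic"). Includes a regex/dictionary note
    extraction layer, predictive-mean-matching and random-forest imputation,
    train-anchored PCA reduction, a repeated multi-fold cross-validation
    harness with seven weighted one-vs-rest metrics, age-sex strata and
    misclassification analyses, and a synthetic-cohort generator so the whole
    pipeline is testable without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    e1071,
    randomForest,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
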