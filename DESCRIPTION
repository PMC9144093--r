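Package: tdmsel
Title: Machine-Learning Model Selection for Bayesian Therapeutic Drug
    Monitoring of Vancomycin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for choosing a population pharmacokinetic (PK) prior for
    Bayesian therapeutic drug monitoring (TDM) of vancomycin.  Simulates
    virtual patients from competing two-compartment infusion models with
    correlated demographics, builds concentration-ratio features, trains
    multiclass classifiers (decision tree, random forest, gradient boosting)
    that map sparse concentration data to the best-matching PK model, and
    predicts 12-24 h drug exposure (AUC) by model selection or
    probability-weighted model averaging, benchmarked against single-model
    and objective-function-value weighted maximum a posteriori (MAP)
    Bayesian estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    xgboost,
    ranger,
    rpart
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    caret,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
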