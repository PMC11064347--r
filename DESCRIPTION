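Package: lateomix
Title: Semi-Supervised Autoencoders and Late Integration for Multi-Omic
    Risk-Factor Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts one-standard-deviation classes of continuous
    cardiovascular risk factors (blood pressure and diastolic-function
    biomarkers) from multi-omic data. Provides a latent-factor synthetic
    cohort generator, training-sample-only preprocessing (target
    residualization, correlation-based transcript filtering, min-max and
    z-score scaling, 1-sd class construction), semi-supervised denoising
    autoencoders with a bi-output reconstruction/prediction loss and a
    matched unsupervised control, Connection-Weights (Olden) variable
    importance, a six-family classifier bank with stratified
    cross-validated tuning, late integration through a cross-omics
    probability tensor and a View Correlation Discovery Network, transfer
    learning of pre-trained encoders to an external hypertension task, and
    macro-F1/AUC/R-squared evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    nnet,
    e1071,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
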