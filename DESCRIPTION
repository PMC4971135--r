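Package: crydx
Title: GMM-UBM Likelihood-Ratio Detection of Newborn Health Conditions from Cry Acoustics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating acoustic detectors of newborn
    health conditions from cry recordings. Implements an MFCC front end with
    delta and acceleration coefficients, diagonal-covariance Gaussian mixture
    modelling with native EM training of universal background models (UBM),
    four UBM adaptation methods (mean-only MAP with a relevance factor, and
    three boosted-mixture-learning variants), duration-normalized
    log-likelihood-ratio scoring with imposter-based HNORM score
    normalization, score-level fusion of expiratory and inspiratory cry
    experts via SVM/MLP/PNN classifiers under repeated stratified K-fold
    cross-validation, DET/EER/AUC evaluation with cost-optimal operating
    points, and a seeded synthetic cry-corpus generator so every stage is
    testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
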