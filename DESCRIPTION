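Package: timbrefuse
Title: Timbre Fusion Analysis for Instrument Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the perceptual fusion of two-instrument
    (dyad) timbres. Implements the full analysis chain used in
    psychoacoustic listening studies of instrument blend: synthesis of
    dyad stimuli and ordinal rating matrices with controlled latent
    structure, reliability and validity screening of listener ratings
    (Cronbach's alpha, standard-deviation outlier filtering with mean
    imputation), Thurstonian scaling by the method of successive
    categories, ANOVA with Student-Newman-Keuls post-hoc grouping,
    attribute correlation and multidimensional preference mapping, a
    45-statistic acoustic descriptor battery (temporal, spectral and
    harmonic families), and cross-validated fusion-prediction models
    (lasso regression, random forests, and a multilayer perceptron).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    car,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
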