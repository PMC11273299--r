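Package: pupasex
Title: Non-Destructive Sex Classification of Silkworm Pupae from Cocoon Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the sex of Bombyx mori pupae without cutting the
    cocoon, from a photograph of the intact cocoon plus its weight.
    Implements FFT-accelerated histogram-of-oriented-gradients (HOG)
    feature extraction with a direct spatial-domain reference path,
    block-wise Fisher linear discriminant compression of the descriptor
    (3780 to 105 features), fusion of a standardized cocoon-weight
    feature, mutual-information-ranked recursive feature elimination,
    a uniform interface to seven classifier families under stratified
    k-fold cross-validation, and hyperparameter optimization of the
    boosted-tree classifier by grid search, a classical genetic
    algorithm, and a teaching-learning-based population-selection
    genetic algorithm (TLBPSGA). Includes a seeded synthetic cocoon
    dataset generator so every stage is testable without proprietary
    rearing-station data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    class,
    rpart,
    randomForest,
    xgboost,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    tiff,
    optparse,
    pROC
Config/testthat/edition: 3
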