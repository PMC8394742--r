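Package: occfall
Title: One-Class Classification Study for Wearable Fall Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for studying one-class (novelty detection)
    classifiers as the decision core of wearable fall detection systems.
    Generates synthetic triaxial accelerometer traces of daily activities and
    falls, extracts twelve peak-centered statistical features from the signal
    magnitude vector, trains five one-class scorers (autoencoder, diagonal
    Gaussian mixture, Parzen window, k-th nearest neighbour distance,
    one-class SVM), and evaluates them with a 2500-point ROC threshold sweep,
    geometric-mean optimal cut-points, stratified 5-fold cross-validation,
    majority-voting ensembles, and a leave-one-activity-category-out
    ablation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
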