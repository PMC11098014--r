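Package: dancekin
Title: Interpretable Kinematic Features and Genre Classification for 3D Dance Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a computational kinematics of full-body movement.
    Reads 3D joint-position sequences (COCO-17 skeleton layout), computes
    Savitzky-Golay smoothed finite-difference kinematics (velocity,
    acceleration, jerk), and encodes each sequence as 17 interpretable
    features spanning sacral movement, extremity dynamics, sacrum-centred
    angular momentum, and body expandedness. Includes a budgeted model-zoo
    search with greedy weighted ensembling under multiclass log loss,
    baseline linear classifiers, post-hoc analyses (truncated-SVD similarity
    embedding, Shapley and permutation feature importance, per-genre
    feature fingerprints, confusion-matrix comparison), and a parametric
    stick-figure motion simulator with analytic feature oracles for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    glmnet,
    ranger,
    xgboost,
    e1071,
    nnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
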