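Package: ddinet
Title: Drug-Drug Interaction Prediction from Fused Drug Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@ddinet.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) from heterogeneous drug
    similarity matrices. Computes a Gaussian Interaction Profile kernel from
    the known-interaction network, selects an informative and non-redundant
    subset of similarity views by an entropy and distance heuristic, fuses
    the selected views with Similarity Network Fusion (iterative KNN-based
    cross-diffusion), and classifies ordered drug pairs with a
    two-hidden-layer feed-forward neural network trained by stochastic
    gradient descent with momentum. Evaluation is by repeated stratified
    five-fold cross-validation with AUC, AUPR and best-threshold
    precision/recall/F-measure, including a nested cross-validation
    hyperparameter search and a self-contained synthetic benchmark
    generator with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
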