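Package: ptqsar
Title: Perturbation-Theory QSAR Models of B-Cell Epitope Activity from
    Star-Graph Entropy Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the activity class of linear B-cell epitopes from
    peptide sequence descriptors mixed with experimental assay conditions.
    Peptide sequences are embedded as star-graph recurrence networks whose
    degree-normalized Markov matrices yield Shannon-entropy descriptors;
    perturbation-theory features encode deviations of query and reference
    descriptors from condition-specific expectations (epitope organism, host
    organism, in vivo process, experimental technique, adjuvant additive).
    Includes a stratified cross-validation AUROC benchmark over seven
    weighted classifiers, a random-forest tree-count scan, impurity-based
    feature-importance ranking, and a synthetic assay-pair generator with
    planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    class,
    e1071,
    rpart,
    randomForest,
    xgboost,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
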