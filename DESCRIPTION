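Package: mdhgi
Title: Matrix Decomposition and Heterogeneous Graph Inference for
    miRNA-Disease Association Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a catalog of
    known associations, disease ontology descriptors and a miRNA functional
    similarity matrix.  The known association matrix is first denoised by an
    l2,1-regularized low-rank self-expressive decomposition solved with
    inexact augmented Lagrange multipliers; the reconstructed matrix is then
    propagated over a heterogeneous similarity graph built from disease
    semantic similarity, miRNA functional similarity and Gaussian interaction
    profile kernels.  Includes global and local leave-one-out and repeated
    k-fold cross-validation harnesses with ROC/AUC reporting, and a synthetic
    data generator with ground truth for recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
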