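Package: clearf
Title: Supervised Feature Scoring via Class-Wise Embedding and
    Reconstruction Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores features of a labelled expression matrix by comparing
    the reconstruction error of a low-dimensional embedding fitted to the
    pooled data with the summed reconstruction errors of embeddings fitted
    separately to each class.  Features whose variation is hard to compress
    across classes but easy to compress within each class receive high
    scores, a continuous surrogate for the mutual information between a
    feature and the class label.  Supports linear PCA and kernel PCA (RBF
    and cubic polynomial kernels) backends, a component-size search anchored
    on the smallest class, a cross-validated SVM benchmark harness over a
    grid of feature counts, and simulation generators for validating the
    entropy/reconstruction-error correspondence and informative-feature
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    kernlab,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
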