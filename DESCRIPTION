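Package: SubLocML
Title: Multi-Label Prediction of Protein Subcellular Localization with
    Ensemble Voting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for multi-label protein subcellular localization:
    integration of heterogeneous labelled protein sources with CD-HIT-style
    redundancy reduction, sequence and profile feature extraction
    (188-dimensional composition/transition/distribution features, 20- and
    420-dimensional PSSM-derived features, pseudo-amino acid composition),
    instance-based multi-label classifiers (MLkNN, BRkNN, IBLR-ML and a
    binary-relevance wrapper over single-label learners), three ensemble
    voting strategies (mean, majority vote, top-K), ranking-based multi-label
    evaluation under seeded k-fold cross-validation, and a synthetic data
    generator with controllable label-composition signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rpart,
    randomForest,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
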