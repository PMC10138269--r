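Package: glocalsvm
Title: Global-Local Least-Squares Support Vector Machines for Imbalanced
    Binary Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-layer least-squares support vector machine (LS-SVM)
    classification for medium-size, class-imbalanced tabular data. The
    training set is partitioned into local regions with k-means, a sparse
    (pruned) LS-SVM is fitted per region, the highest-support-value points
    of every region are merged into a reduced pool, and a single global
    LS-SVM is trained on that pool. Includes the plain LS-SVM solver
    (bordered KKT linear system), support-value pruning, grid
    cross-validation tuning, a repeated shuffled-split evaluation protocol
    with minority-positive confusion metrics and Welch t-test comparison,
    a seeded synthetic imbalanced benchmark generator, CSV input/output,
    JSON model archives and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
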