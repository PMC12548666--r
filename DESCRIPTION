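Package: sfcoupling
Title: Structure-Function Coupling of Brain Networks via Regularized
    Partial Correlation and Cross-Modularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers functional connectivity from region-by-time activity
    recordings with six regularized correlation and partial-correlation
    estimators (linear shrinkage to the identity or to a group mean,
    eigenvalue clipping and its cautious variant, the graphical lasso, and
    rotationally invariant eigenvalue cleaning), selects the regularization
    strength by validation-set likelihood, sparsifies connectivity at the
    percolation threshold, and compares functional and structural graphs
    across their whole hierarchy of nested partitions with the
    cross-modularity statistic (Newman modularity combined with adjusted
    normalized mutual information). Includes a synthetic-cohort generator
    with a planted modular Gaussian graphical model, paired structural
    matrices and a planted transcriptome, population-level experiment
    drivers, bootstrap partition stability, and disease gene-set module
    Z-scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
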