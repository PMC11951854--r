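Package: clustermatch
Title: Clustermatch Correlation Coefficient for Numerical and Categorical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Clustermatch Correlation Coefficient (CCC), a
    clustering-based, not-only-linear correlation coefficient for pairs of
    numerical and/or categorical variables. Each variable is converted into a
    set of candidate partitions (quantile-based clusters for numerical values,
    categories for categorical values) and the coefficient is the maximum
    adjusted Rand index over all partition pairs, clamped at zero. Includes
    permutation-based significance testing with Benjamini-Hochberg adjustment,
    a deterministic parallel driver for pairwise gene co-expression matrices,
    expression-matrix preprocessing (log transform, top-variance gene
    selection), simulation generators for canonical relationship patterns
    (Anscombe quartet, quadratic, two-lines, non-coexistence, categorical
    mixtures, clustered substructure), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
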