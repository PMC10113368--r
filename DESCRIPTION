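Package: factorpat
Title: Mining Factor-Specific Patterns in Drug-Induced Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies, for each gene in a cell-line by compound grid of
    dichotomized differential-expression calls, the factor-specific pattern
    (the union of a subset of cell-line rows and compound columns) that
    minimizes the Hamming pattern distance to the observed profile. Patterns
    are found by exhaustive enumeration on small grids or by a genetic
    algorithm on large ones, assessed against grouped permutation null
    distributions with Benjamini-Hochberg false discovery rate control, and
    exported as a gene / cell-line / compound association network. Includes
    readers for GCT, TSV and HDF5 z-score matrices, a tensor assembler for
    signature metadata, and a synthetic-data generator with planted patterns
    for calibration and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rhdf5
Config/testthat/edition: 3
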