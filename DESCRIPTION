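Package: hicbound
Title: Spectral Detection and Differential Analysis of TAD Boundaries in Hi-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects boundaries of topologically associated domains (TADs) in
    chromosome-specific Hi-C contact matrices using a spectral-clustering
    derived eigenvector-gap statistic, and compares boundaries between
    conditions. Boundary scores are Z-scores of log eigenvector gaps under a
    log-normal model; a standardized differential boundary score classifies
    per-bin changes into complex, split, merge, shifted and strength-change
    types. Supports consensus boundary calling across replicates (median
    scores), six-pattern classification of boundary dynamics over time
    courses, permutation tests for colocalization of boundaries with genomic
    annotation tracks, and a synthetic Hi-C generator with planted domain
    structure for validation. Reads dense, sparse-triplet and
    coordinate-annotated text contact matrices and writes BED-style results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
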