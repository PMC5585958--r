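Package: mirset
Title: Unbiased miRNA Functional Enrichment Analysis with Bitset Set Algebra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo (empirical p-value) functional enrichment analysis for
    groups of miRNAs. Target gene sets of miRNA groups are represented as
    fixed-width bitsets; group unions are computed by bitwise-or and
    category overlaps by bit-probing, making one-million-permutation runs
    tractable. Includes a naive hash-set reference engine, Benjamini-Hochberg
    FDR marking, the classic hypergeometric (Fisher) comparator, a synthetic
    interaction/annotation generator with tunable target correlation, and a
    command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
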