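Package: cvbarcode
Title: Multi-Locus Composition Vector Distances for Plant DNA Barcoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free analysis of multi-locus DNA barcoding datasets
    using the composition vector (CV) method: sparse K-string frequency
    vectors per sequence, cosine ("projection") correlation distances
    D = (1 - C)/2 per locus, a pairwise sequence-length-weighted combination
    of per-locus distance matrices, neighbor-joining tree construction, and
    monophyly-based grouping-effectiveness evaluation with best-K selection
    by scanning K = 6..20. Includes a synthetic multi-locus dataset generator
    with known genus/species/individual structure, FASTA and PHYLIP
    distance-matrix I/O, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
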