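Package: hapalocompare
Title: Comparative Analysis of Hapalindole-Family Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing hapalindole, ambiguine and welwitindolinone
    (hpi/amb/wel) biosynthetic gene clusters from Subsection V cyanobacteria:
    GenBank/GFF3 cluster parsing and summaries, affine-gap global pairwise
    alignment and percent identity, single-linkage homolog-family assignment
    with an identity threshold, transcript (operon) prediction from gene
    orientation, PROSITE-style degenerate motif scanning, rule-based cluster
    classification, neighbour-joining 16S phylogeny with bootstrap monophyly
    testing, exact-mass utilities for the indole-isonitrile intermediate, and
    a seeded synthetic-data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
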