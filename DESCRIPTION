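Package: segforest
Title: Joint Overlap of Multiple Genomic Interval Sets via Segment Tree
    Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds jointly overlapping regions of n genomic interval sets
    given in BED format, with no constraints on the inputs (intervals may
    be unsorted, duplicated, nested or overlapping within a set). Pairwise
    intersections are answered by a segment tree with canonical subsets,
    or by an indexed segment tree forest: the segment tree is cut at a
    data-driven depth, the resulting short trees are doubly linked in
    coordinate order and hash-indexed by their start coordinate, and
    collisions are resolved with balanced binary search trees. An n-way
    divide-and-conquer combiner reduces the joint overlap of n sets to
    pairwise intersections, processed per chromosome. Includes a
    semi-synthetic dataset generator (uniform fixed-length intervals over
    human-scale chromosomes), adversarial fixture generation, and an
    independent brute-force oracle used for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    parallel,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    S4Vectors,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
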