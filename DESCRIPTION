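Package: gcmalign
Title: Divide-and-Conquer Multiple Sequence Alignment via Graph Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalable multiple sequence alignment by recursive
    divide-and-conquer. Sequences are decomposed into subsets with a guide
    tree (centroid edge decomposition), subsets are aligned independently
    (built-in progressive aligner or an external tool), and the
    subalignments are merged with a graph clustering merger: backbone
    alignments spanning the subsets are compiled into a weighted alignment
    graph, clustered with Markov clustering, and the clusters are ordered
    into a valid merged alignment. Also provides conservative lossy
    alignment compression by column dissolution, sum-of-pairs alignment
    error metrics (SPFP/SPFN), a file-based resumable task runtime for
    multi-process execution, and a synthetic sequence-evolution simulator
    with known true alignments for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
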