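Package: wgt
Title: Recognizing, Generating, Indexing and Visualizing Wheeler Graphs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with Wheeler graphs, the class of edge-labeled
    directed graphs that admit a Burrows-Wheeler-style index. Implements the
    Wheelie recognition algorithm, which combines an iterative renaming
    heuristic with either an exhaustive permutation solver or an integer
    difference logic (IDL) constraint solver to decide whether a graph admits
    a Wheeler ordering; a brute-force recognizer and an O/I/L-array
    enumeration baseline for ground truth at small scale; generators for
    tries, De Bruijn graphs, pseudo-De Bruijn graphs, reverse deterministic
    graphs built from multiple sequence alignments, and complete, random and
    d-NFA Wheeler graphs; construction of the succinct O/I/L index arrays for
    recognized graphs; and a two-row bipartite visualization in which a valid
    Wheeler ordering shows zero same-label edge crossings. Graphs are read
    and written in DOT format and alignments in gapped FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
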