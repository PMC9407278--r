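Package: ladderpath
Title: Ladderpath Decomposition and Complexity Indices for Strings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes ladderpaths of strings and string systems: hierarchical
    decompositions into reused building blocks ("ladderons"), together with
    the three associated complexity indices -- the size-index S, the
    ladderpath-index lambda (minimal construction cost in lifts), and the
    order-index omega = S - lambda (lifts saved by reuse).  Provides exact
    branch-and-bound and longest-repeat heuristic searches for shortest
    ladderpaths, generation-path simulation, validation of user-supplied
    ladderpaths, a canonical partially-ordered-multiset text notation,
    Graphviz DOT laddergraph export, plain-text and FASTA input, synthetic
    string generators with planted hierarchy, and an independent brute-force
    oracle for cross-checking on small inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, Biostrings, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
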