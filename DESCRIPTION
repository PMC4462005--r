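Package: qgmapper
Title: All-Mapping of Short Reads with Q-Gram Filtration and Packed Banded
    Bit-Vector Verification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An all-mapper for short sequencing reads: finds every location
    in a reference genome where a read aligns within an edit-distance
    threshold k. Candidate locations are generated by pigeonhole q-gram
    filtration over a hash index of the reference, and verified with a
    banded Myers bit-vector algorithm whose per-pattern state is packed
    into wide machine words so that one read is scored against several
    candidate windows simultaneously. Includes SAM output, a synthetic
    read simulator with truth tracking, and a Rabema-style sensitivity
    evaluator backed by a brute-force dynamic-programming oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
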