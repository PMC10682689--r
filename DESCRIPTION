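Package: ancestrylink
Title: Local Ancestry Tract Extraction from Succinct Tree Sequence Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts tracts of local ancestry from succinct tree sequence
    node and edge tables given a set of census ancestors. Provides a fast
    single-pass link-ancestors engine implemented in C++, a naive per-tree
    reference engine, population annotation and squashing of ancestry
    segments into contiguous tracts, a forward-time Wright-Fisher admixture
    simulator with recombination and census recording for generating valid
    test data, and command-line entry points for the full
    simulate-trace-squash pipeline. Tables are read and written in the
    tab-separated text dialect used by tree sequence tools, and tracts can
    be exported as CSV and BED.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
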