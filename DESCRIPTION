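Package: intrarep
Title: Detection and Statistics of Intragenic Repeat Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Locates all repeat pairs within a single gene-scale sequence or
    between two sequences: forward and reversed (inverted) repeats, perfect
    and degenerate, with exact positions, alignments and identities, using
    iterated Smith-Waterman local alignment with path masking. Also provides
    a maximal exact repeat finder (repeat-match style), a sliding-window
    dot-matrix comparator (dotter style), per-position repeat depth profiles,
    the repeat density index rho, identity-interval histograms, containment
    detection between sequences, a seeded synthetic sequence generator with
    planted repeats of controlled divergence, and a batch command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
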