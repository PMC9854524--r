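Package: slimscan
Title: Short Linear Motif Discovery by Glocal Alignment with
    Conservation and Enrichment Profiling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans protein databases for short linear motifs (SLiMs)
    similar to query peptides using semi-global ("glocal") affine-gap
    alignment with BLOSUM50 scoring: global over the query, local over
    the target, in the manner of GLSEARCH. Alignment significance is
    estimated with an empirical extreme-value (Gumbel) model calibrated
    on shuffled-composition sequences. Hit sets are deduplicated into
    unique motif collections, summarised as position frequency matrices,
    consensus notations with bracketed alternates, and sequence-logo
    information content, then profiled by taxonomic category and by
    hypergeometric GO-term enrichment with Benjamini-Hochberg FDR and
    fold enrichment. A synthetic-data generator plants profile-drawn
    motifs and configurable GO enrichment into simulated databases with
    an exact truth table, supporting end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: SequenceMatching, Alignment, MotifDiscovery, GeneSetEnrichment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
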