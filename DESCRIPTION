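Package: docarray
Title: Document Array Profiles for Pangenome Document Listing and Read
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a run-length Burrows-Wheeler index over a collection of
    documents (for example strain genomes or groups of related genomes)
    augmented with document array profiles: longest-common-prefix vectors
    sampled at BWT run boundaries that turn a completed backward search into
    a full document listing by scanning d integers, instead of locating every
    occurrence of the pattern.  Provides the single-scan streaming
    construction of the sampled profiles, two reference constructions used as
    oracles, a truncated-width variant for bounded match lengths,
    maximal-exact-match extraction from reads, a MEM-weighted read classifier
    together with a one-document-per-match baseline, and a synthetic
    pangenome and long-read simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
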