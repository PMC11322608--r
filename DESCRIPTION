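Package: condsigr
Title: Detection of Condensate-Like Chromatin-Associated Protein Co-Occupancy Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects condensate-like chromatin-associated protein (CAP)
    co-occupancy signatures (CondSigs) from collections of ChIP-seq peak sets
    and condensation-related protein annotations. Builds a genome-wide binary
    occupancy matrix over 1 kb bins, segments it per focus CAP, fits biterm
    topic models with automatic topic-number selection to context-specific
    sub-matrices, calls co-occupancy signatures, scores their condensation
    potential with six annotation-derived features via AUROC, and removes
    redundant signatures. Includes protein-level annotations (net-charge-per-
    residue charged blocks, phase-separation score clustering), peak and
    domain post-processing, and a fully synthetic data generator with planted
    signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
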