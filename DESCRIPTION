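Package: droughtmiR
Title: MicroRNA Discovery and Digital Differential Expression from Small RNA Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for microRNA gene discovery from deep-sequenced
    small RNA libraries: adapter trimming and unique-read collapsing, contaminant
    filtering, exact and bounded-mismatch mapping, hairpin precursor prediction under
    five structural and read-support criteria (minimum free energy, duplex mismatches,
    asymmetric bulges, strand bias, precise processing), single-linkage family
    clustering, position-dependent penalty scoring of miRNA:target duplexes, and
    digital differential expression with the Audic-Claverie exact test on TPTM
    normalized counts. Includes a bundled nearest-neighbor RNA folding engine with a
    pluggable external backend, and a synthetic small RNA library simulator with
    planted hairpin loci for validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
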