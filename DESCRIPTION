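Package: ocascan
Title: Orthocaspase Survey of Cyanobacterial Proteomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects p20-like caspase-homologue (peptidase C14) sub-domains in
    cyanobacterial proteomes with a position-specific scoring profile and
    affine-gap local alignment, classifies catalytic histidine-cysteine dyad
    variants (wild-type orthocaspases versus mutated pseudo-variants),
    extracts the flanking specificity pockets and derives degenerate consensus
    patterns, predicts transmembrane segments by Kyte-Doolittle hydropathy,
    assembles whole-protein accessory-domain architectures and membrane
    topology calls, computes per-strain and per-group abundance statistics,
    and builds dyad-labelled neighbour-joining phylogenies with clade-purity
    reports. A synthetic-proteome generator with a full ground-truth table
    makes every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
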