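Package: bzipr
Title: Rule-Based Characterization of bZIP Transcription Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the systematic, rule-based characterization of plant
    bZIP transcription factor families from protein sequences and gene
    models. Anchors the bZIP basic/hinge/leucine-zipper region via the
    invariant N-x7-R/K-x9 motif and establishes the conventional signed
    position numbering (-18..-1, +1..); classifies DNA-binding specificity
    groups from basic/hinge residues with a configurable rule table;
    assigns coiled-coil heptad registers (a-g) and classifies inter-helical
    g-e' electrostatic pairs to predict homo-/heterodimerization and
    dimerization subfamilies; computes intron splicing phases from CDS
    coordinates and classifies conserved intron patterns within the
    basic/hinge window; detects tandem gene clusters; summarizes
    family-level register composition; and provides 2^-ddCt relative
    expression with Pearson/average-linkage clustering for qRT-PCR tables.
    A seeded synthetic-family generator with planted ground truth supports
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
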