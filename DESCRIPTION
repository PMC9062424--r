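Package: rippmine
Title: Radical-SAM Anchored RiPP Genome Mining and Mass-Spectrometric Verification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline pipeline for discovering ribosomally synthesized and
    post-translationally modified peptide (RiPP) biosynthetic pathways anchored
    on radical-SAM enzymes: sequence similarity network construction and
    clustering under E-value/identity/length thresholds, gene-neighborhood
    extraction around anchor genes, six-frame scanning of flanking windows for
    unannotated precursor peptide ORFs, tandem-repeat and residue-class motif
    detection with progressive multiple alignment, a peptide monoisotopic-mass
    engine (terminal amidation, isotope labels, cyclopropylglycine -2 Da
    events, b/y/internal fragment ladders, ppm errors, modification-site
    localization), Beer-Lambert assay arithmetic, and a seeded synthetic-data
    generator providing planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
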