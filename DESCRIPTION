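Package: structkit
Title: Tidy Structural Bioinformatics for Protein Modeling and Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for macromolecular structure handling aimed at
    protein modeling and engineering. Parses PDB and mmCIF coordinate files
    into atom-level tibbles, assigns secondary structure with an internal
    Kabsch-Sander hydrogen-bond method or from DSSP output, extracts
    super-secondary structure motifs (smotifs) with their four-parameter
    loop geometry (D, hoist, packing, meridian), grafts loops between
    proteins by flank superposition, computes protein-protein and
    protein-nucleic residue-contact interfaces, filters homology-search
    hits (including the Rost significance curve) and writes PIR alignments
    for comparative modeling. Ships deterministic generators of ideal
    helices, strands, hairpins, two-element scaffolds and synthetic dimers
    so the whole toolkit is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
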