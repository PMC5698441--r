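Package: camsite
Title: Mapping and Characterization of 1-4-7-8 Calmodulin-Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for locating and characterizing calmodulin (CaM)
    recognition sites of the 1-4-7-8 class, in which hydrophobic anchor
    residues at relative positions 1, 4, 7 and 8 of a short mixed
    alpha/3-10 helix engage both CaM lobes. Provides position-specific
    scoring matrix construction and proteome scanning for candidate
    sites; filtering, deduplication, classification and hot-spot
    triangulation of cross-linking mass spectrometry link tables;
    backbone dihedral analysis, alpha versus 3-10 helix classification,
    backbone hydrogen-bond detection, anchor spacing and hydrophobic
    face coherence for bound peptide helices; Shrake-Rupley solvent
    accessible surface area, interface burial and Kabsch superposition
    for structure copies; Hill-type and cooperative Michaelis-Menten
    fitting of concentration-response curves; and seeded synthetic-data
    generators (ideal helices, proteomes with planted motifs, crosslink
    tables, noisy binding curves) with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
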