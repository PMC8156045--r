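Package: pxreg
Title: Lipid Specificity and Phosphoregulation Analysis of PX Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how phosphorylation regulates
    phosphoinositide-reading Phox homology (PX) domains. Computes the Lipid
    Specificity Index (LSI) from phosphatidylinositol phosphate (PIP) ligand
    sets, calls membrane-interactive residue clusters from per-residue
    membrane-docking score profiles, maps consensus membrane-binding Site
    windows through gapped alignments, aggregates phosphoproteomic records
    into citation-binned PIP-Stop Scores (PSS), and tests the association
    between lipid specificity and phosphoregulation with a permutation test.
    Ships a transcription of the published human and yeast PX domain panel
    and a seeded synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
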