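Package: gstome
Title: Structural Analysis of Multigene Glutathione Transferase Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the comparative structural analysis of a multigene
    enzyme family such as an organism's glutathione transferase (GST) complement.
    Reads heavy-atom structure models (experimental or predicted, with pLDDT
    confidence in the temperature-factor column) and a precomputed multiple
    sequence alignment, and provides alignment-indexed conservation, gap and
    charge analytics; conformational comparison through Kabsch superposition,
    per-residue Calpha deviation, coarse-grained backbone angles and chi1
    rotamer distances; contact-based detection of the dimerization interface
    and cofactor binding sites, single-linkage ligand clustering and
    Shrake-Rupley buried interface areas; shortest-path communication pathways
    between the two cofactor sites of a homodimer; and thermal B-factor
    prediction from a parameter-free all-heavy-atom anisotropic network model.
    Seeded synthetic-data generators emulate predicted homodimers, ligand
    ensembles and alignments so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
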