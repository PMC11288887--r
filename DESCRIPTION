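Package: buttress
Title: Parametric Design of Helical Repeat Proteins with Buttressed Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry engine for de novo design of tandem helical repeat
    proteins whose long inter-helix loops are rigidified ("buttressed") by
    hydrogen-bond networks. Provides parametric repeat-backbone generation
    from rigid-body degrees of freedom, beta-turn and helix-capping motif
    mining with K-centers clustering, kinematic long-loop closure and
    propagation, hydrogen-bond based loop filters and scores (intraloop and
    interloop bond counts, direction score, hydrophobic motif score),
    bidentate sidechain-to-backbone hydrogen-bond scanning with constrained
    rescue of near-miss geometries, buried-unsatisfied-polar counting, and
    design-versus-experiment Calpha RMSD comparison. Models are read and
    written as PDB; an end-to-end seeded pipeline emits backbone models and
    machine-readable filter reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
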