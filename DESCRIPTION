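Package: hingeflex
Title: Conformational Flexibility Analysis of Receptor Linker ("Hinge") Regions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for characterizing the flexibility of disordered linker
    (hinge) regions in multidomain receptors from conformational ensembles,
    such as molecular dynamics trajectories of the thyroid-stimulating-hormone
    receptor (TSHR). Provides multi-model PDB input/output and an atom
    selection language; steric-clash detection with element-dependent
    distance thresholds; mutually-proximal inter-domain contacts;
    geometric hydrogen-bond detection with per-residue-pair occupancy
    tracks, sequence-separation and occupancy filtering, and track-saturation
    diagnostics; pairwise backbone RMSD maps with k-medoid clustering and
    minimax cluster representatives; Calpha-based helix-axis geometry
    (end-to-end length, bend radius, inter-helix distances and angles) with
    a range-based significance flag; Kabsch-Sander secondary-structure
    assignment and per-residue timelines; radius-of-gyration and
    principal-axis orientation descriptors; a rigid-body two-domain assembly
    heuristic (anchor superposition, Z-rotation scan minimizing the enclosing
    box, contact-breadth selection); and a synthetic-structure generator
    (ideal and bent helices with full backbones, random coils, rigid-body
    rotation trajectories, clash and hydrogen-bond fixtures) so that every
    analysis stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, bio3d, yaml
Suggests: testthat (>= 3.0.0), cluster, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
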