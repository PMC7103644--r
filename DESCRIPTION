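Package: memborient
Title: Orientation, Contact and Clustering Analytics for Membrane-Protein Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trajectory analytics for membrane-embedded proteins such as the
    voltage-gated sodium channel beta subunits: rigid-body domain orientation
    from the principal axes of the mass-weighted moment-of-inertia tensor with
    Tait-Bryan (intrinsic ZYX) angle extraction, transmembrane helix tilt,
    Kabsch-superposed RMSD, backbone dihedrals, residue-lipid and
    protein-protein contact occupancy, single-linkage oligomer clustering over
    protein copies, and radial distribution functions of lipids around a
    protein.  Includes readers and writers for PDB and GRO structures and
    multi-model PDB / DCD trajectories, a periodic minimum-image distance
    core, and a seeded synthetic-scene generator (rigid bodies on programmed
    orientation schedules, ideal helices, bilayer surrogates, multi-copy
    scenes with planted oligomers) so every analysis stage is testable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    bio3d,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
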