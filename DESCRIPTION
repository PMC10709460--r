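Package: cdtraj
Title: Trajectory Analysis of Cyclodextrin Host-Guest Inclusion Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conformational and thermodynamic analysis of molecular-dynamics
    trajectories of cyclodextrin host-guest systems. Provides rim-geometry
    descriptors of the macrocycle (rim areas, circularity, heights, cavity
    volume), gyration-tensor shape descriptors (relative shape anisotropy,
    asphericity), cavity hydration shell counts and radial distribution
    functions, geometric hydrogen-bond detection with lifetime estimation,
    guest binding kinetics and orientation classification, thermodynamic
    integration and Bennett acceptance ratio free-energy estimators with a
    thermodynamic-cycle composition for binding free energies, and
    two-dimensional free-energy landscapes over collective variables.
    Includes a synthetic-system generator with known ground truth so every
    analysis stage can be validated without running molecular dynamics, and
    readers/writers for multi-model PDB, GRO, and tabular lambda-window
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
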