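Package: dockflex
Title: Headless Flexible-Receptor Molecular Docking Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable engine for interactive-style rigid and flexible
    receptor-ligand docking. Computes 12-6 Lennard-Jones and screened Coulomb
    forces and energies within a cutoff using a regular-grid neighbor search,
    detects collisions by force-magnitude thresholding or van der Waals
    maximum-penetration, models receptor conformational change under ligand
    forces by linear response in a truncated covariance eigenbasis built from
    a coordinate ensemble, detects hydrogen bonds with geometric
    (McDonald-Thornton) criteria, triangulates the solvent-excluded surface
    via a distance field and Marching Cubes, and drives headless docking
    sessions with rigid-body moves, collision gating, component toggles,
    ghost regions, distance monitors, energy traces, path record/replay and
    complex export. Reads PDB and mmCIF structures; writes PDB, OBJ/PLY
    meshes and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
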