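Package: pamnet
Title: Physics-Aware Multiplex Graph Neural Networks for 3D Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds two-layer multiplex graphs (local and global interaction
    layers) from 3D molecular structures and fits physics-aware multiplex
    message-passing neural networks on them. Supports E(3)-invariant scalar
    property regression, E(3)-equivariant dipole-moment prediction through
    per-node geometric vectors, RNA structural-model scoring, and
    protein-ligand binding affinity prediction with weight-sharing replica
    networks. Includes readers for SDF, QM9-style XYZ and PDB structures,
    task-specific preprocessing (atomization-energy references, heavy-atom
    filters, binding-pocket extraction), synthetic fixture generators, and a
    small reverse-mode automatic differentiation engine used for training.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
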