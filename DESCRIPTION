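Package: ccgeom
Title: Conformational Descriptors for Coiled-Coil Receptor Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric analysis of helical-bundle transmembrane receptor
    dimers, of the kind used to dissect signal transduction in sensor
    histidine kinases. Implements TWISTER-style local helix axis fitting,
    per-residue Crick angles with circular statistics, intra- and
    cross-protomer C-alpha distance descriptors, axial (piston)
    center-of-mass projections, phi/psi-based linker secondary-structure
    state, and backbone hydrogen-bond classification (alpha versus 3-10),
    evaluated on static structures and over trajectory windows. A seeded
    synthetic generator builds ideal helices and four-helix dimers in two
    conformational states with known imposed rotation, scissoring, piston,
    and linker-break parameters, providing ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'ccgeom-package.R'
    'structures-io.R'
    'helix-geometry.R'
    'crick.R'
    'descriptors.R'
    'geometry-utils.R'
    'synthetic.R'
    'pipeline.R'
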