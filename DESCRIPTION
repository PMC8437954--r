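Package: dynhelix
Title: Helical Geometry and Elastic Energetics of Dynamin Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the mechanics of dynamin helical assemblies:
    conversions among cryoEM helical-symmetry parameters, continuous helix
    shape and curvature/twist; the stalk-filament elastic energy model and its
    (radius, pitch) landscape with one-start versus multi-start comparisons;
    axisymmetric Helfrich membrane-tube energetics; a coarse-grained
    bead-filament-on-membrane passive relaxation simulator; and rigid-body
    superposition, hinge-angle and interface-conservation operators for
    comparing filament conformations from coordinate files. Synthetic fixture
    generators allow every analysis to run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'cli.R'
    'membrane-model.R'
    'helix-geometry.R'
    'elastic-model.R'
    'constriction-sim.R'
    'dynhelix-package.R'
    'structure-compare.R'
    'synthetic-fixtures.R'
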