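Package: preorg
Title: Solution-Phase Preorganization Analysis of Solute Dimers Around
    Crystal Growth Modifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how a crystal growth modifier reorganizes
    neighboring planar solute molecules from pi-stacked to coplanar,
    crystal-compatible dimer conformations in molecular configuration
    ensembles. Implements the (r, theta, psi) dimer order-parameter
    framework, stacked/coplanar conformer classification with hydrogen-bond
    contact criteria, near-modifier versus bulk population selection,
    probability and differential probability maps, free-energy maps,
    crystal-lattice-derived geometric fingerprints with conforming-dimer
    enrichment, modifier-aligned spatial distribution function occupancy
    grids with isosurface component analysis, hydrogen/heavy-atom contact
    frequency tables, and a seeded synthetic rigid-body ensemble generator
    that emulates the statistical structure of stacked-dominant solutions
    templated by a planar modifier. Reads and writes multi-frame XYZ,
    multi-model PDB, and OpenDX volumetric grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
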