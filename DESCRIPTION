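Package: restenosim
Title: Hexagonal-Grid Agent-Based Simulation of Post-Angioplasty Restenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale multiscale simulator of arterial wall remodeling after
    balloon angioplasty. Provides an anisotropic hyperelastic (two fiber
    family) constitutive library with continuum matrix/fiber damage and an
    elastoplastic ductile-damage plaque surrogate; hexagonal-lattice
    cross-section geometry with contour extraction and lofting; damage- and
    wall-shear-stress-derived stimulus fields; a probabilistic agent-based
    model of smooth muscle cell and extracellular matrix dynamics driving
    lumen remodeling; a synthetic vessel/damage/shear generator emulating the
    post-intervention state; and restenosis metrics with rank-sum statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
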