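Package: corneafem
Title: Finite-Element Simulation of Intracorneal Ring Segment Implantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional finite-element modelling of the human cornea for
    the simulation of intracorneal ring segment (ICRS) implantation.  Builds a
    layered meridional cross-section (epithelium, anterior and posterior
    stroma) between two circular arcs, meshes it with 8-node serendipity
    quadrilaterals, and solves the small-strain elastic problem in either an
    axisymmetric or a plane-strain idealization with transversely isotropic
    layer materials, intraocular pressure on the posterior surface and
    layer-wise pre-strains.  An in-silico implantation procedure carves a
    stromal tunnel, maps its boundary onto the triangular cross-section of a
    ring segment, binds the ring outline as a rigid body and lets it settle
    axially.  Post-processing computes sagittal (axial) curvature maps,
    best-fit spheres and dioptric change summaries, so that symmetric and
    asymmetric ring designs with variable thickness and base width can be
    compared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    dplyr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
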