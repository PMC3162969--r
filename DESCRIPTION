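Package: gohbiax
Title: Anisotropic Hyperelastic Modelling of Collagen Scaffold Biaxial
    Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterisation of collagen gel scaffolds from planar
    equibiaxial tension and parallel-plate rheometry. Implements the
    Gasser-Ogden-Holzapfel (GOH) fiber-dispersion strain-energy function
    with exact Cauchy stresses for incompressible membranes under plane
    stress; reduction of raw biaxial records (fiducial marker quads plus
    axial loads) to Cauchy stress versus logarithmic strain and
    tangent-modulus curves; a two-stage constrained least-squares protocol
    that fits isotropic parameters to nonaligned scaffolds and fiber
    orientation and dispersion to aligned ones; oscillatory rheometry sweep
    summaries; and fully seeded synthetic-data generators for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
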