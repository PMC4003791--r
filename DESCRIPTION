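Package: mobiir
Title: Model-Based Iterative Image Reconstruction for Diffuse Optical
    Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fully three-dimensional diffuse optical tomography (DOT) on
    tetrahedral finite-element meshes.  Provides a Galerkin finite-element
    forward solver for the continuous-wave photon-diffusion equation with
    Robin boundary conditions, adjoint-method sensitivity (Jacobian)
    matrices, Broyden rank-1 quasi-Newton Jacobian updating, and a
    regularized Levenberg-Marquardt model-based iterative image
    reconstruction (MoBIIR) loop.  Includes a deterministic cylindrical
    mesh generator, synthetic optical phantoms with absorbing
    inhomogeneities, a circular source-detector scan geometry, a
    multiplicative Gaussian measurement-noise model, and mesh/matrix
    input-output in Gmsh MSH v2.2 ASCII, VTK legacy ASCII and Matrix
    Market formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
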