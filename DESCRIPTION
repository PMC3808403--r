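Package: fascitrace
Title: Laplacian Flux-Based Reconstruction of Skeletal Muscle Fascicle
    Architecture
Version: 0.1.0
Authors@R:
    person("fascitrace", "developers", email = "fascitrace@example.org",
           role = c("aut", "cre"))
Description: Reconstructs skeletal-muscle fascicle arrangements from a
    volumetric simplicial mesh of the muscle shape. The Laplace equation is
    solved with a cell-centered finite-volume scheme under uniform-flux
    Neumann boundary conditions on the tendon attachment areas, yielding a
    conservative face-flux field. Fascicle tracts are traced element by
    element through that field with a flux-consistent barycentric streamline
    algorithm, then spline-smoothed and resampled to compute fascicle
    lengths and pennation angles. Includes Gmsh MSH input, VTK output,
    deterministic synthetic muscle geometries (strip, fan, annulus sector,
    box) with closed-form field oracles, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
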