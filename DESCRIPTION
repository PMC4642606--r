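Package: warpscaling
Title: Scale-Aware Analysis of Landmark Shape Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the spatial scaling of landmark-based shape
    variation. Implements generalized Procrustes superposition, thin-plate
    spline interpolation and bending energy in two and three dimensions,
    principal and partial warps, bending-energy deflation of Procrustes
    shape distributions to a spatially self-similar null, estimation of the
    integration scaling dimension by log-log regression of partial warp
    variance on specific bending energy (with an optional nugget term for
    digitizing noise), and relative intrinsic warps. Includes seeded
    simulators for the isotropic offset Gaussian (Mardia-Dryden) shape
    model, its bending-deflated self-similar counterpart, and a hierarchical
    parcellation process, together with readers and writers for TPS and CSV
    landmark files and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
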