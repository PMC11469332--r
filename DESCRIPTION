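Package: ropecoil
Title: Liquid Rope-Coil Coating Design and Porous Implant Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and quantification tools for multi-scale
    porous silicone coatings deposited by the liquid rope-coil (LRC) effect.
    Provides a parametric model of viscous-thread coiling (regime
    classification, loop frequency and amplitude laws, trochoid centerline
    generation), toolpath planners for planar substrates, scanned height-map
    surfaces and rotary mandrels with G-code export, a filament deposition
    simulator producing voxel volumes and levelset isosurface meshes, the
    associated macro/micro pore morphometry pipeline (mesh curvature, 2D void
    analysis, height maps, window/level particle analysis), stereological
    estimators for capsule thickness, volume fractions and vessel metrics,
    ink formulation arithmetic, and seeded synthetic-data generators with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
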