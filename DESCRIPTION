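Package: spinecage
Title: Topology Optimisation and In Silico Subsidence Testing of Spinal
    Fusion Cages on Voxel Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for designing anatomically and mechanically
    conforming interbody fusion cages by density-based topology optimisation
    on structured voxel grids, and for assessing their subsidence risk in
    silico.  Includes a structured-grid hexahedral linear-elastic finite
    element solver, a robust three-field (eroded/nominal/dilated) compliance
    minimisation with a bone principal-strain constraint and a local volume
    constraint for porous infill, QCT-style density-to-modulus material laws,
    a factor-of-fracture-risk (FFR) principal-strain assessment with a
    bilinear elasto-plastic bone model, a seeded synthetic functional-spinal-
    unit phantom generator, implant morphology metrics (porosity, pore
    diameter, iso-surface export to STL), and quantitative credibility
    studies (mesh convergence, sensitivity analyses) with cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
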