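Package: vpatch
Title: Pre-Surgical Planning of Arterial Patch Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale simulator for planning patch angioplasty of stenosed
    great arteries (e.g. the main pulmonary artery in Tetralogy of Fallot
    repair). Generates parametric stenosed-vessel shell meshes, performs the
    virtual surgery sequence (pressure-equivalent residual stress, incision,
    traction-controlled gap opening, tangent-patch synthesis, suturing,
    post-operative pressurization) with a quasi-static corotational
    triangular thin-shell finite-element solver, fits linear-elastic patch
    material constants from planar biaxial test data, and computes
    biomechanical and reduced-order hemodynamic performance indices
    (centerline area profiles, residual stenosis, centerline offset,
    von Mises stress summaries, suture-line stress mismatch, Reynolds and
    pressure-drop estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
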