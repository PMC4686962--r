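Package: wssphantom
Title: Propagation of Lumen Reconstruction Errors into Coronary Wall Shear
    Stress Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how small errors in the reconstructed
    lumen of a mildly diseased coronary bifurcation propagate into wall
    shear stress (WSS) metrics. Generates parametric bifurcation phantoms
    with a concentric area stenosis, emulates reader segmentation errors as
    smooth correlated radial perturbations, synthesizes pulsatile WSS vector
    fields with an analytic quasi-steady surrogate flow model (Poiseuille-type
    wall shear with Carreau viscosity, diameter-based outflow split, and a
    post-stenotic recirculation crescent), computes time-averaged WSS, the
    oscillatory shear index, low-WSS areas and their Dice similarity, unwraps
    surface fields onto an axial-by-circumferential bin grid, and performs
    margin-based equivalence testing (two one-sided tests) with
    percentage-of-equivalence summaries per vessel region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
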