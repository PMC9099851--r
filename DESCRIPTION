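Package: stentflow
Title: Hemodynamics and OCT Metrics of Stented Coronary Bifurcations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale pipeline comparing left-main bifurcation stenting
    strategies in silico. Builds parametric 2D longitudinal bifurcation lumens
    with strut obstacles per strategy (KIO, KBI, BD-DES), meshes them with
    boundary-refined triangles, solves steady incompressible Newtonian flow
    with a stabilized finite-element method, and reduces the shear-rate field
    to high-shear area (>1000 1/s) and maximum shear rate. A synthetic-cohort
    generator calibrated to published OCT medians/IQRs drives strut apposition
    classification, elliptical index and thrombus-area metrics, and a
    nonparametric statistics layer (median/IQR, Kruskal-Wallis with tie
    correction and exact small-sample permutation p, Dunn's post-hoc test).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
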