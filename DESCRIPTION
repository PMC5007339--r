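Package: actoflow
Title: Contraction Analysis and Active-Gel Modelling of Disordered Actomyosin Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying light-activated contraction of disordered
    actomyosin networks from particle-image-velocimetry (PIV) velocity fields:
    divergence and radial/tangential flow decomposition about an activation
    region, strain timecourses with lag/linear/plateau phase segmentation,
    force-balance inversion of radial network stress, and Hill-equation
    cooperativity fitting of maximum strain against myosin thick-filament
    density. Includes a radially symmetric active Kelvin-Voigt gel solver
    with a time-ramped contractile stress in a disc, a reduced-scale
    agent-based simulator of semiflexible filaments and bipolar motor thick
    filaments with load-dependent kinetics, and synthetic-data generators
    that emulate the PIV pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
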