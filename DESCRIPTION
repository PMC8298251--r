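Package: plaquemech
Title: Mechanical Model Comparison for Coronary Plaque Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element analysis of atherosclerotic coronary plaque
    cross-sections segmented from intravascular ultrasound. Implements
    anisotropic modified Mooney-Rivlin hyperelastic wall models solved as
    quasi-static 2D plane-strain or thin-layer variants under follower
    lumen pressure, recovery of the no-load geometry by iterative
    circumferential shrink with a fixed 10 percent axial shrink-stretch, a
    fully-developed-flow surrogate for lumen wall shear stress, a seeded
    generator of synthetic IVUS-like vessel cohorts, and pointwise
    model-comparison statistics (plaque wall stress/strain and flow shear
    stress relative errors) aggregated at slice, patient and cohort level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
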