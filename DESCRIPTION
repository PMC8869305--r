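Package: kneedamage
Title: Continuum-Damage Finite-Element Analysis of Knee Ligaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static nonlinear finite-element analysis of the four principal
    knee ligaments (ACL, PCL, MCL, LCL) with a fiber-reinforced
    Holzapfel-Gasser-Ogden hyperelastic law and localized, history-dependent
    continuum damage driven by maximum fiber stretch. Includes a parametric
    synthetic knee surrogate (tetrahedral ligament struts between rigid bone
    frames), calibration of constitutive parameters to uniaxial stress-stretch
    data, a staged loading protocol (quadriceps damage induction, anterior
    shear, tibial torque) across damage scenarios, and mid-substance von Mises
    stress summaries with VTU field export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
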