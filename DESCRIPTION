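Package: fibrolink
Title: Non-Local Myocyte-Fibroblast Coupling in 2D Cardiac Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monodomain simulation of two-dimensional cardiac tissue in
    which a diffusively uncoupled scar is electrically bridged to the
    surrounding myocardium by randomly generated, spatially non-local
    myocyte-fibroblast gap-junction links. Implements the ten
    Tusscher-Panfilov (2006) human ventricular myocyte model
    (shallow-restitution parameter set) and the MacCannell active
    fibroblast model with calibrated resting potentials, a Poisson
    link-topology generator with a Euclidean distance constraint, pacing
    protocols (edge, point, S1S2), and analyses of action potential
    duration restitution, APD dispersion and reentrant-wave regime
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
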