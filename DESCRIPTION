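Package: chemosmooth
Title: Continuum Simulation and Analysis of Chemotactic Smoothing of
    Bacterial Fronts in Porous Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a Keller-Segel continuum model of collective
    bacterial migration through porous media, with Michaelis-Menten
    nutrient consumption, logarithmic (receptor-saturating) nutrient
    sensing, density-dependent motility with jamming, and cell
    proliferation.  The coupled reaction-diffusion-chemotaxis system is
    integrated with a conservative finite-difference scheme and an
    Adams-Bashforth-Moulton predictor-corrector time stepper (compiled
    core).  Analysis tools extract the leading edge of migrating fronts,
    quantify the exponential decay of morphological undulations
    (smoothing time tau), decompose the chemotactic velocity into
    driving force and response-function contributions, and estimate the
    valley-to-peak catch-up time.  Experiment drivers reproduce knockout
    simulations, wavelength and pore-size sweeps, sensing-function
    variants, and low-nutrient robustness checks, and generate all
    synthetic inputs (undulated inocula, amplitude series, image
    stacks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    pracma,
    withr,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
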