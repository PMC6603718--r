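Package: hydrofuse
Title: Hybrid NIR and Cobalt-Electrode Calibration for Phosphate Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibration toolkit for estimating phosphate (PO4) concentration
    in hydroponic nutrient solutions from two complementary sensor channels:
    transmission near-infrared (NIR) spectra and cobalt ion-selective
    electrode potentials (EMF). Provides spectral pretreatments (moving
    average, standard normal variate, multiplicative scatter correction),
    principal component regression and NIPALS partial least squares with
    10-fold cross-validation, log-linear (Nikolsky-Eisenman form) electrode
    calibration, a feed-forward neural network with back-propagation and
    Levenberg-Marquardt training, and feature-level sensor fusion that feeds
    principal-component scores plus raw EMF into the network (PC-NN). A
    synthetic sensor simulator generates Beer-Lambert style spectra and
    near-Nernstian electrode responses so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
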