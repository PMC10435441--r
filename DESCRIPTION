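Package: ppgsweat
Title: Optical Skin Modelling and Detection of Sweat-Film Formation in Wrist PPG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Photon-packet Monte Carlo simulation of light transport in a
    seven-layer optical model of human skin with a topical water/sweat film,
    tailored to a four-wavelength (535/645-940/970/1450 nm) wrist
    photoplethysmography (PPG) sensor, together with the downstream signal
    analysis pipeline: a synthetic multi-channel PPG + IMU run-recording
    generator with known ground truth, windowed time-domain and generalized
    Morse wavelet features, paired-window (run start versus run end)
    gradient-boosted tree classifiers with Shapley feature ranking, and a
    trend-slope detector for the onset of sweat-film formation on the
    1450 nm water-absorption band.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
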