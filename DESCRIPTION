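Package: optospiral
Title: Optogenetic Control of Spiral Waves in Simulated Cardiac Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates two-dimensional optogenetically modified mouse
    ventricular tissue and the control of spiral-wave re-entry by global
    sub-threshold illumination.  Couples the Bondarenko mouse ventricular
    ionic model to a four-state channelrhodopsin-2 photocurrent in a
    monodomain reaction-diffusion solver with compiled kernels, and provides
    open-loop periodic and closed-loop resonant-feedback illumination
    protocols together with spiral-tip tracking, rotation-frequency
    estimation and meander-pattern classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
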