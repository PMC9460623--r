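Package: mhfocus
Title: Antenna-Excitation Optimization for Microwave Breast Hyperthermia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hyperthermia treatment planning for phased microwave breast
    applicators. Generates heterogeneously dense synthetic breast dielectric
    phantoms, computes per-antenna unit-excitation complex vector fields with a
    ray-averaged cylindrical-wave model (or imports externally solved fields),
    forms heating-potential maps by superposition, trains a two-stage
    convolutional network (phases from a masked target map, then per-channel
    voltages) with sine/cosine phase encoding, and scores excitations with
    target-energy fraction, dominant-hotspot fraction, hotspot-to-target ratio
    and average target power deposition at a fixed 6 W total input power.
    Brute-force phase and voltage look-up-table baselines are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
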