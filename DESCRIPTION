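Package: auxinpulse
Title: Compartmental Modelling and Pulse-Shape Analysis of Polar Auxin Transport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic modelling of auxin pulse transport through plant
    tissues. Provides intercellular flux laws (polar plus diffusion-like,
    carrier-based, Michaelis-Menten saturating, asymmetric lateral),
    closed-form pulse kinetics (velocity and spreading rate) with inverse
    inference of the diffusion-to-polar permeability ratio and diffusion
    bounds, an explicit-time-step simulator of auxin concentration on a grid
    of axial compartments across laterally coupled channels, gaussian and
    peak-region ("maximal fit") pulse-shape estimation, a synthetic
    segment-count data generator, and named scenario presets for the
    single-channel, coupled-channel, vacuole and saturating-lateral models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
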