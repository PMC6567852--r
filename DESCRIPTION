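Package: srkchan
Title: Single-Channel Kinetics of Sarcoplasmic Reticulum Potassium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of planar lipid bilayer recordings of
    sarcoplasmic reticulum K+ (TRIC) channels. Provides a ground-truthed
    bilayer-current simulator (continuous-time Markov gating rendered into
    noisy, Gaussian-filtered, digitized traces), constrained segmental
    k-means idealization with a merged noisy subconductance class, event
    post-processing (short-event stripping, open probability, mean open
    times, current-voltage regression), log-binned dwell-time distributions
    with left-truncated exponential-mixture maximum likelihood and
    likelihood-ratio selection of the number of components, binomial
    occupancy analysis of multichannel records, and level decomposition of
    recordings that contain both a ryanodine receptor and K+ channels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
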