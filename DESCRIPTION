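Package: tdeflow
Title: Spiking Time-Difference Encoders for Event-Based Motion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, supervised training, and evaluation of spiking
    time-difference encoders (TDE-2 and the inhibition-augmented TDE-3) for
    motion detection from event-camera data. Includes a synthetic event-camera
    stimulus generator with Poisson background-activity noise, a spatio-temporal
    correlation filter for event denoising, backpropagation-through-time
    training with surrogate gradients for spike-count and inter-spike-interval
    velocity decoding, direction-channel optical-flow and yaw ego-motion
    pooling, and the associated evaluation metrics (direction-selectivity index,
    fraction of true activity, angular and endpoint flow errors, rotation
    errors).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
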