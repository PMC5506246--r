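Package: colliculus
Title: Spiking Neural Network Model of the Superior Colliculus Motor Map
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: One-dimensional spiking neural network model of the midbrain
    superior colliculus (SC) that converts a static saccade-target location
    into a dynamic population burst encoding saccade kinematics. Two layers
    of adaptive exponential integrate-and-fire (AdEx) neurons on a log-polar
    motor map are coupled by conductance-based synapses and Mexican-hat
    lateral connectivity implementing a soft winner-take-all. Includes the
    parameter-identification procedures (brute-force single-neuron grid
    search with an iso-spike-count contour fit, and a genetic algorithm for
    lateral weight scales), burst-profile analysis tools (spike-density
    functions, cross-correlations, movement fields), and a dynamic linear
    ensemble decoder that turns population spikes into eye-position and
    eye-velocity traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
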