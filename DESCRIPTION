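Package: colliculus
Title: Spiking Neural-Network Model of the Superior Colliculus Motor Map
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional, two-layer spiking neural network of
    the midbrain Superior Colliculus (SC) motor map. A cortical input layer of
    adaptive exponential integrate-and-fire (AdEx) neurons is driven by a
    separable Gaussian-gamma external current and projects one-to-one onto an
    SC output layer whose biophysical parameters (adaptation time constant,
    feedforward weight, lateral-interaction gain) follow rostral-caudal
    gradients. Tuned Mexican-hat lateral connectivity normalizes the recruited
    SC population, and a linear spike-vector decoder converts SC spike trains
    into saccadic eye trajectories. Includes the spatial and temporal
    input-variation sweep protocols, spike-density and burst metrics, and
    main-sequence kinematic fits (saturating amplitude-peak-velocity relation
    and the linear peak-velocity-times-duration versus amplitude law).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
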