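Package: neurocrit
Title: Criticality and Computation in Plastic Spiking Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of current-based leaky integrate-and-fire
    neurons whose synapses follow a homeostatic plasticity rule (positive weight drift
    plus anticausal spike-timing-dependent depression), and provides the full analysis
    stack used to place such networks relative to a critical point: neuronal-avalanche
    extraction with discrete truncated power-law maximum likelihood fits and
    finite-size scaling of the cutoff, branching-ratio and autocorrelation-time
    estimation, trial-to-trial van Rossum distances and perturbation susceptibility,
    plug-in information-theoretic measures (entropy, lagged mutual information, memory
    capacity, active information storage, transfer entropy, and partial information
    decomposition via the convex minimum-synergy optimization), and reservoir-computing
    benchmarks (n-bit parity, n-bit sum, NARMA) with linear readouts. The number of
    input synapses per neuron acts as the control parameter for the distance to
    criticality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
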