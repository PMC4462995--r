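Package: impednet
Title: Leaky Integrate-and-Fire Networks with a Stochastic Response-Failure
    Impedance Mechanism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates excitatory leaky integrate-and-fire networks in which
    each neuron converts threshold crossings into evoked spikes only
    probabilistically, with a history-dependent response-failure probability
    governed by an exponential forgetting kernel over recent inter-crossing
    intervals.  Above a neuron-specific critical frequency these failures act
    as a low-pass filter that saturates the mean inter-spike interval at the
    critical period, and on a network level suppresses firing rates toward
    the lowest neuronal critical frequency.  Provides the single-neuron
    failure model and network engine, prototypical one-pre/one-post network
    topologies with supplemental connections, stimulation protocols and
    analytic predictors, a closed-loop latency-stabilization controller with
    a phenomenological latency responder, statistical procedures for failure
    sequences (pattern probabilities, run-length laws, forgetting-exponent
    fits), sub-sample threshold-crossing interpolation with noise
    propagation, and plain-text input/output for topologies, schedules,
    event logs and latency traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
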