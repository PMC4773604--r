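Package: cerebstdp
Title: Distributed Spike-Timing-Dependent Plasticity in a Closed-Loop
    Cerebellar Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clock-driven simulation of a spiking cerebellar microcircuit
    (mossy fibers, granule cells, Purkinje cells, climbing fibers, deep
    cerebellar nuclei) equipped with spike-timing-dependent plasticity at
    three synaptic sites: parallel fiber to Purkinje cell, mossy fiber to
    deep nuclei, and Purkinje cell to deep nuclei.  The model is embedded
    in two closed-loop motor-learning benchmarks: a one-dimensional
    set-point tracking task and feed-forward torque correction of a
    simulated three-link arm carrying a payload.  Provides analysis tools
    for weight profiles, learning consolidation (counter-phase transfer),
    gain trajectories, spike-train cross-correlograms, convergence speed,
    and error-reduction metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
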