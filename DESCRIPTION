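Package: dendspike
Title: Hodgkin-Huxley and Dendritic Calcium Spike Neurons with Fixed-Point
    and Lookup-Table Arithmetic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single-compartment Hodgkin-Huxley soma and a
    two-compartment soma plus dendrite neuron whose dendrite generates
    calcium action potentials (dCaAPs) with input-strength-dependent
    amplitude, enabling single-neuron XOR computation. Integration uses
    backward Euler exploiting the conditional linearity of the membrane
    equations. The whole simulator can run in emulated 32-bit fixed-point
    arithmetic (s16.15 accum and u0.32 fract with round-to-nearest and
    saturation) and with lookup-table approximations of the gating kinetics
    and of the dCaAP waveform, mirroring how such models are deployed on
    neuromorphic digital hardware without floating-point units. Includes a
    cross-arithmetic validation harness (voltage-error and spike-time
    metrics over current sweeps, lookup-table resolution studies), a
    battery of ten neurocomputational firing features, and a single-neuron
    XOR experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
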