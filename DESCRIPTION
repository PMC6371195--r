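Package: spiklip
Title: Information-Theoretic Intrinsic Plasticity for Spiking Neurons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for intrinsic plasticity in leaky
    integrate-and-fire (LIF) neurons. Implements the SpiKL-IP adaptation rule,
    which tunes a neuron's leaky resistance and membrane time constant online so
    that the distribution of its output firing rate approaches the
    maximum-entropy exponential distribution with a chosen mean, by stochastic
    descent on a KL-divergence surrogate built on the closed-form firing-rate
    transfer function of the LIF neuron. Includes a millisecond-lockstep
    simulator for single neurons and recurrent networks, a calcium-trace firing
    rate estimator, Poisson input generation, dense and distance-dependent
    (liquid-state-machine style) reservoir builders, exponential-fit and
    KL-divergence diagnostics, the voltage-threshold intrinsic-plasticity
    baseline rule, and reproducible experiment drivers with CSV/JSON output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
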