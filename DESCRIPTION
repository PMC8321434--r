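Package: spikeprop
Title: Probabilistic Spike Propagation for Rate-Coded Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of feed-forward integrate-and-fire
    spiking neural networks with probabilistic spike propagation: synaptic
    weights are reinterpreted as propagation probabilities normalized by
    per-cluster maximum weights, spikes are served through sorted-weight
    early termination or a cumulative-histogram termination-point lookup,
    and a lane-based accelerator cost model tallies synaptic updates,
    categorized memory accesses, cycles (synchronous and asynchronous spike
    serving) and a parametric energy estimate. Includes a synthetic network
    generator with heavy-tailed per-neuron weight distributions, potentiation
    ledgers for convergence analysis, and sweep drivers over cluster counts
    and histogram resolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
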