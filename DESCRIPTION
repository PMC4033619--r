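Package: criticgate
Title: Confidence-Weighted Hebbian Actor-Critic Decoding for Brain-Machine Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for a two-choice actor-critic brain-machine
    interface decoder trained by Hebbian reinforcement learning. The actor is a
    three-layer binary-node network updated by an associative reward-penalty
    rule; the critic delivers noisy evaluative feedback of configurable
    accuracy together with a per-trial confidence term that weights the update.
    Includes an Izhikevich spiking-neuron generator for two-state synthetic
    neural sessions with controllable class overlap, a pseudo-real-time input
    normalizer, study harnesses for critic-accuracy and stimulus-noise sweeps
    with paired statistics and stability counts, and file round-tripping for
    sessions and results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
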