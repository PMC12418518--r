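Package: ebll
Title: Energy-Based Local Learning for Graph-Structured Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training neural networks with energy-based local
    learning rules instead of backpropagation. Networks are represented as
    graphs of nodes (state holders) and typed edges (feedforward, feedback,
    skip and recurrent parameterized mappings). The package implements
    hierarchical predictive coding, bidirectional predictive coding with a
    combined feedforward/feedback prediction-error energy, equilibrium
    propagation over a Hopfield energy, a unified internal/external energy
    decomposition, and a layer-adaptive learning-rate optimizer, together
    with diagnostics for gradient explosion and vanishing during the
    inference phase. Includes synthetic classification data generators,
    readers for MNIST IDX and CIFAR binary batch files, and a small
    command-line interface for reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
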