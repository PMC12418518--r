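# ebll: energy-based local learning for graph-structured neural networks

Backpropagation trains neural networks by propagating error derivatives
through the whole computation graph — something biological synapses, which
see only their local neighbourhood, cannot do. Energy-based local learning
(predictive coding, equilibrium propagation) replaces it with descent on a
scalar energy `F = E + βC` over unit states and parameters: an **inference
phase** relaxes the states to an energy minimum, then a **learning phase**
updates each parameter from quantities local to its edge. `ebll` is an R
toolkit for this family, aimed at computational-neuroscience and
machine-learning researchers who want exact, inspectable desk-scale
implementations of these dynamics.

Networks are graphs of **nodes** (state holders) and typed **edges**
(feedforward, feedback, skip, recurrent mappings — fully connected,
convolutional, pooling, or composites). The package implements:

* **Hierarchical predictive coding (HPC)** — internal energy
  `E = Σᵢ εᵢ²` with feedforward errors `εᵢ = vᵢ − gᵢ(vᵢ₋₁)`; inference
  `dvᵢ = 2εᵢ − 2εᵢ₊₁ ∂gᵢ₊₁/∂vᵢ`, learning `dθᵢ = −2εᵢ ∂gᵢ/∂θᵢ`.
* **Bidirectional predictive coding (BiPC)** — weight-tied feedback
  predictions (transposed convolutions / matrix transposes) give every node
  a second error `εᵇ`; the additive energy `Σ (εᶠ)² + (εᵇ)²` and the
  combined energy `Σ (εᶠ + εᵇ)²`, whose signed cancellation stabilizes
  inference gradients in deep networks.
* **Equilibrium propagation (EP)** — Hopfield energy
  `E = ½Σ‖vᵢ‖² − ½Σᵢ≠ⱼ ρ(vᵢ)wᵢⱼρ(vⱼ) − Σ bᵢρ(vᵢ)`, free and nudged phases,
  contrastive update `(1/β)(∂E/∂θ|nudged − ∂E/∂θ|free)`.
* **LALR** — a layer-adaptive learning rate `ηᵢ = η·S/‖dθᵢ‖₂` with `S` the
  harmonic mean of the per-layer gradient norms, equalizing every layer's
  update magnitude.
* **Diagnostics** — per-node gradient-norm traces along the inference loop
  (gradient explosion/vanishing probes), weight-to-gradient ratio reports,
  and per-layer gradient-fluctuation series.
* **Data plumbing** — seeded synthetic generators (Gaussian blobs, toy
  glyph images), MNIST IDX and CIFAR binary-batch readers, YAML run
  configurations, JSON-lines metrics logs, and a small CLI
  (`inst/cli/ebll`) with `gen-data`, `train`, `probe-gradients`,
  `compare-optimizers` and `validate` subcommands.

All gradients are exact analytic derivations, validated against central
finite differences (relative error ~1e-8) — there is no autodiff behind
the curtain.

## A worked example

```r
library(ebll)

ds  <- make_synthetic(synthetic_spec("blobs", n_samples = 1000,
                                     n_classes = 2, seed = 0))
g   <- build_graph("toy_chain", depth = 2, width = 8, n_classes = 2,
                   input_shape = 2)
fit <- ebll_train(g, ds, run_config(method = "bipc_combined",
                                    optimizer = "lalr", epochs = 20, seed = 0))
fit
#> <ebll_fit> method bipc_combined, optimizer lalr, 20 epochs
#>   final loss 0.1565, test accuracy 0.960

tail(fit$metrics$accuracy, 3)
#> [1] 0.960 0.960 0.960
```

A two-hidden-layer chain trained purely by local energy descent reaches
96.0% held-out accuracy on two Gaussian classes whose centers sit four
noise standard deviations apart (Bayes optimum ≈ 97.7%); the backprop
baseline on the identical graph reaches 97.5%. Per-epoch loss, accuracy,
mean equilibrium energy and per-layer gradient norms are in `fit$metrics`
and `fit$grad_norms`; `predict()`, `coef()`, `residuals()` and `plot()`
work as for any fitted model.

The explosion diagnostic in two lines:

```r
probe <- probe_gradient_norms("hpc", recurrent_T = 5, eta_v = 0.01)
probe_growth_ratio(probe, node = 6)   # deep-node growth per seed: ~11-14x
```

Under the same conditions the combined bidirectional energy's deep-node
gradient norms *decay* (ratio ≈ 0.06) — the stabilization the bidirectional
model exists for.

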