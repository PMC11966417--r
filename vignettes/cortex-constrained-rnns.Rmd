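---
title: "Cortex-constrained recurrent networks: models, constraints and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortex-constrained recurrent networks: models, constraints and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsernn)
```

## The question

Cortical circuits differ from conventional artificial neural networks in
three interpretable structural ways: connectivity between neurons is very
sparse, it is recurrent rather than feedforward, and every neuron is either
excitatory or inhibitory and stays that way (Dale's principle), with
inhibitory neurons a small minority (about 11.5% in sensory cortex). This
package isolates the functional consequences of those three features by
construction: it builds recurrent networks whose hidden layer has a random
binary connectivity mask drawn at a fixed connection probability $p$,
optionally constrains each hidden node's outgoing weights to a fixed sign,
trains them under time- and data-limited regimes, and measures both how
well they learn and how they represent their inputs.

## Model

Each network has a single hidden layer of $N$ nodes. An input sequence
$x_1, \dots, x_T$ (each $x_t \in \mathbb{R}^d$) drives the recurrence

$$h_t = \phi(x_t W_{in} + h_{t-1} W_{hh}), \qquad h_0 = 0,$$

with $\phi$ either ReLU (the default; nodes need net excitation above
threshold to produce output, like neuronal integration) or tanh (a control
with no threshold). Only the final hidden state is read out, linearly:
$z = h_T W_{out}$, one logit per class; predictions are the argmax with
ties broken toward the lowest class index. Images enter as sequences by
row-wise slicing: one image row per timestep, so a 28×28 grayscale image
gives $T = 28$, $d = 28$, and an RGB image interleaves the three channel
values per pixel ($d = 3w$). Intensities are divided by the format maximum
(255) to land in $[0,1]$; absolute activation magnitudes reported by the
analyses are therefore on that normalized scale.

**Sparsity.** $W_{hh}$ is elementwise masked by a binary matrix sampled
once per network: each ordered pair of distinct nodes is connected
independently with probability $p$. Self-connections are excluded, which
makes the expected density $E/[N(N-1)]$ equal $p$ exactly — the density
formula divides by $N(N-1)$, which is only consistent with a loop-free
graph. Masked weights are exactly zero at all times; the optimizer step is
followed by a projection that resets them to zero. The input and readout
layers are always fully connected.

**Dale's principle.** When enabled, `round(f N)` nodes (default
$f = 0.115$) are marked inhibitory; the count is exact rather than
binomial so the stated fraction holds deterministically. Every outgoing
weight of a hidden node — its row of $W_{hh}$ *and* its row of $W_{out}$ —
carries the node's sign. The input weights are unconstrained: input nodes
have no excitatory/inhibitory identity. During training, any outgoing
weight whose update would reverse its node's sign is set to zero instead
of crossing; it remains trainable and may later move away from zero in the
permitted direction.

**Initialization.** Hidden-layer weights are uniform on $(-b, b)$ with
$b = 0.001$; under Dale, a magnitude uniform on $(0, b)$ times the node's
sign, with inhibitory magnitudes optionally scaled (ten-fold in the
strengthened-inhibition manipulation). The input and readout weights use
the same uniform bound by default, because the hidden-layer scheme is the
only one stated for the original protocol and using one scheme everywhere
keeps the comparison between architectures clean; a `kaiming` option
(uniform on $\pm\sqrt{1/\mathrm{fan~in}}$) is available for sensitivity
checks. Biases are off by default and, when enabled, exempt from the Dale
constraint. The feedforward control splits the $N$ hidden nodes into two
equal layers (the split is not specified more precisely anywhere, and
50/50 is the only symmetric choice), applies the connection probability to
the inter-layer weights, and receives the whole input flattened at once.

## Training

Minibatch Adam (learning rate 0.001, PyTorch-default moments) on softmax
cross-entropy, targets one-hot. Batch size defaults to 100 — unstated in
the original protocol, and a conventional value; it is configurable.
Training data are reshuffled every epoch under the run seed, so every run
is bit-reproducible. After each optimizer step the mask projection runs
first, then the Dale sign clip; Adam's moment estimates are *not* reset
when a weight is clipped, the simplest projection consistent with "set to
zero instead". Test accuracy is evaluated on the full test split after
every epoch. Early stopping (optional) halts when test accuracy has not
improved for a configurable number of consecutive epochs (the exact
stopping rule of the original data-limited protocol is unstated; 5 is a
reasonable patience at 50-epoch budgets); for
delay measurements training can instead stop as soon as accuracy first
exceeds chance plus margin, since nothing after the first crossing affects
the delay. The `sparse_to_dense` mode uses the mask only at
initialization — weights that start at zero may become nonzero — to test
whether sparse *initialization* rather than sparse *constraint* drives the
observed effects.

Two details are deliberate interpretations of ambiguous points. Whether
the original implementation shuffled per epoch is unstated; we shuffle,
seeded, because unshuffled minibatch order couples batch composition to
class layout in the file. And gradients returned by `network_gradients()`
are raw (including masked positions); masking happens in the projection,
so the finite-difference oracle can check every coordinate of the
backpropagation.

## The training-delay metric

Dense Dale networks with a cortex-like excitation–inhibition imbalance can
sit at chance accuracy for many epochs before learning starts. Two related
quantities describe a trace: `first_above_chance`, the 1-based index of
the first epoch whose test accuracy exceeds $1/C + \text{margin}$, and
`delay_epochs`, the number of epochs *before* that crossing
(`first_above_chance - 1`). The second is the headline metric: a network
that learns immediately has delay 0, and a trace that never crosses gets
the sentinel `"never"` (`Inf`). The margin defaults to 0.02 above chance —
the crossing is plotted without a stated tolerance in the source protocol,
and 0.02 is small enough not to miss slow learners yet large enough that
binomial noise on a 500-sample test set (sd ≈ 0.013 at chance) rarely
crosses it spuriously. A `sustained` option requires two consecutive
epochs above threshold for noisy traces.

## Representation analyses

All analyses operate on the final-timestep activations — the only vector
the readout sees.

- **Nonzero fractions** count, per input, the hidden nodes with strictly
  positive output: how distributed the code is.
- **Pairwise mutual information** uses the first Kraskov k-nearest-
  neighbour estimator ($k = 3$, the default of the commonly used
  implementation) on randomly sampled distinct node pairs, reported in
  nats. A vanishing uniform jitter ($10^{-10}$ of the sample scale) breaks
  ties so the estimator is well defined on discretized or ReLU-saturated
  data; a zero-variance node gives MI 0 by definition; small negative
  estimates are clipped to 0 with the clipped count reported.
- **Initialization correlations** are Pearson coefficients between node
  activation vectors over a probe set, computed before any training;
  constant nodes are excluded and counted. Pairs are subsampled (10,000 by
  default, seeded) when $\binom{N}{2}$ is infeasible, mirroring the MI
  pair-sampling protocol.
- **Test-time dropout** zeroes a random `round(fraction × N)`-node subset
  of the final-step outputs, resampled independently for every sample
  (matching a per-image protocol), with no rescaling of survivors.
  Fraction 0 reproduces the undropped evaluation bit-exactly; fraction 1
  zeroes all logits, and the tie rule then forces class 0 everywhere.
  Monotonicity in the fraction is *not* asserted anywhere — it is not
  guaranteed.

## The synthetic task generator

The generator stands in for row-scanned image benchmarks so the whole
pipeline is testable without downloads. Per class it draws one fixed
non-negative $T \times d$ template (a `template_sparsity` fraction of
entries uniform on $[0.5, 1]$, the rest zero — mostly dark, like digit
images); each sample is the template shifted in time by a uniform jitter,
plus Gaussian noise, clipped to $[0, 1]$. What it shares with normalized
pixel rows: bounded non-negative inputs, class-dependent structure
localized in time, within-class variability. What it does not emulate:
within-class style variation beyond translation, pixel correlations, or
anything like natural image statistics — so passing tests demonstrate the
mechanics and the relative orderings (sparse vs dense, balanced vs
imbalanced), not absolute benchmark accuracies.

Defaults, chosen once: 10 classes, $T = 28$, $d = 28$ (the grayscale
benchmark geometry), noise sd 0.1, jitter ±2 rows, 2000 training samples
(200 per class — within the 50–1000-per-class range of the data-limited
protocol, and enough optimizer steps per epoch that a 256-node sparse
network exceeds 80% test accuracy within 5 epochs) and 500 test samples.

## Problem sizes and numerical choices

The analyses and checks in this package run at desk scale on one CPU:
networks up to $N = 2048$, the synthetic task above, 3–10 seeds per
configuration. The mechanisms of interest are orderings (dense vs sparse
activation magnitude and correlation at initialization, presence vs
absence of a training delay, tanh vs ReLU gradient magnitude), which
transfer across scale; the absolute values reported at $10^4$-node
benchmark scale do not. A separate "reproduction" configuration of the
grid functions can encode the full-size protocol but is intended for GPU
reimplementation, not for running here.

Numerical details worth knowing: cross-entropy uses the log-sum-exp
stabilization, so enormous Dale-network activations do not overflow;
ReLU's subgradient at exactly zero is taken as 0; `matched_parameter_grid`
breaks ties in the edge-budget error toward the larger (sparser) network;
training aborts with a diagnostic on non-finite loss; and every stochastic
step (mask, signs, weights, shuffling, pair subsampling, dropout subsets,
jitter) is seeded, so any row of any results table is re-derivable from
its spec and seed alone.

## Checkpoints and logs

Checkpoints (spec, mask, signs, weights, trace) are single hierarchical
RDS files via `save_checkpoint()`/`load_checkpoint()`; per-epoch logs are
line-delimited JSON (`write_trace_jsonl()`) or CSV. A thin command-line
wrapper over the exported functions lives in
`system.file("scripts", "sparsernn-cli.R", package = "sparsernn")` with
`generate-data`, `train`, `grid` and `analyze` subcommands.

## A worked example

```{r example, eval = FALSE}
task <- make_task(synthetic_task_spec())

spec <- connectivity_spec(256, 0.1, seed = 0)
net <- build_network(spec, input_dim = 28, n_classes = 10)
fit <- train_network(net, task$train, task$test,
                     training_config(max_epochs = 5, seed = 0))
fit$trace$test_accuracy
#> 0.150 0.224 0.598 0.828 0.850

rec <- record_activations(fit$params, task$test)
nonzero_fraction(rec)$mean
pairwise_mutual_information(rec, n_pairs = 2000, seed = 0)$mean
dropout_robustness(fit$params, task$test, c(0, 0.5, 0.9), seed = 0)
```

## Known limitations

- Absolute performance numbers at $10^4$-node, full-benchmark scale are
  out of reach on a CPU and are not claimed; only desk-scale orderings are
  tested.
- The Dale delay at $N \approx 1000$ on the synthetic task is short (0–2
  epochs) and seed-dependent; the dense-vs-sparse ordering is the robust
  observable, and it grows with network size.
- The k-NN MI estimator is biased for strongly dependent pairs at small
  sample sizes; tests bound its error against an exhaustive histogram
  oracle on discretized data at the sample sizes actually used.
- No attempt is made at biologically plausible *learning* (backpropagation
  only), structured wiring (degree correlations, motifs), spiking dynamics
  or conductance noise.
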