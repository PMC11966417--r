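# sparsernn

Sparse, recurrent, Dale-constrained neural networks in R — a pipeline for
asking what cortex-like structural constraints do to learning and to neural
representations.

Cortical circuits are very sparsely connected, heavily recurrent, and made
of neurons that are each exclusively excitatory or inhibitory (Dale's
principle), with inhibitory cells a small minority (~11.5% in sensory
cortex). Conventional ANNs are none of these things. `sparsernn` builds
recurrent networks that impose these features one at a time and measures
the consequences for time-limited learning, data-limited learning, and the
structure of the learned representations.

## The model

A single hidden layer of `N` nodes runs the recurrence

    h_t = phi(x_t W_in + h_{t-1} W_hh),   h_0 = 0,

with `phi` ReLU (default) or tanh, and a linear readout from the final
hidden state only: `logits = h_T W_out`. Structural knobs:

- **Sparsity**: each directed edge between distinct hidden nodes exists
  independently with connection probability `p`, drawn once as a binary
  mask; masked weights are exactly zero throughout training. With
  self-loops excluded the expected density `E/[N(N-1)]` equals `p`. A
  network is called sparse at `p <= 0.1`.
- **Recurrence**: a two-layer feedforward control splits the same `N`
  nodes into two layers, applies `p` to the inter-layer weights, and sees
  the input flattened at once.
- **Dale's principle**: each hidden node is fixed excitatory or inhibitory
  (`round(f N)` inhibitory, default `f = 0.115`); all its outgoing weights
  (hidden-hidden and readout rows) carry its sign; any update that would
  flip a sign sets the weight to zero instead.

Training is minibatch Adam (lr 0.001) on softmax cross-entropy, with the
mask and Dale projections applied after every step. Weights initialize
uniformly in (-0.001, 0.001) (Dale: magnitude in (0, 0.001) times the
node's sign). Analyses operate on the final-timestep activations: nonzero
fractions, activation magnitudes, pairwise mutual information (Kraskov
k-NN estimator, k = 3, nats), Pearson correlations at initialization,
test-time dropout robustness, and the training delay (epochs spent at
chance before accuracy exceeds `1/C + margin`).

Images become sequences by row-wise slicing (one image row per timestep);
an IDX (MNIST-format) reader is included, and a built-in generator
produces row-scanned-image-like synthetic tasks so everything runs with no
downloads.

## Worked example

```r
library(sparsernn)

task <- make_task(synthetic_task_spec())        # 10 classes, T=28, d=28
spec <- connectivity_spec(256, 0.1, seed = 0)   # sparse recurrent net
net  <- build_network(spec, input_dim = 28, n_classes = 10)
fit  <- train_network(net, task$train, task$test,
                      training_config(max_epochs = 5, seed = 0))
fit$trace$test_accuracy
#> [1] 0.150 0.224 0.598 0.828 0.850
```

The trace shows time-limited learning: 15% test accuracy after one pass
over the 2000 training sequences, 85% after five. Representation metrics
from the same fit:

```r
rec <- record_activations(fit$params, task$test)
nonzero_fraction(rec)$mean            # fraction of nodes speaking per input
pairwise_mutual_information(rec, n_pairs = 2000, seed = 0)$mean  # nats
dropout_robustness(fit$params, task$test, c(0, 0.5, 0.9), seed = 0)
```

Dale-constrained comparisons, e.g. the training delay induced by the
cortex-like E/I imbalance in dense but not sparse networks:

```r
dv <- delay_vs_size(sizes = 1024, p_values = c(1, 0.1), task,
                    training_config(max_epochs = 8, stop_at_accuracy = 0.12),
                    n_seeds = 3)
dv$summary
```

A thin CLI over these functions (subcommands `generate-data`, `train`,
`grid`, `analyze`) is installed at
`system.file("scripts", "sparsernn-cli.R", package = "sparsernn")`.

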