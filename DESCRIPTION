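Package: sparsernn
Title: Sparse Recurrent Neural Networks with Cortex-Like Connectivity Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, training and analysis of recurrent neural networks
    constrained by interpretable structural features of cortical circuits:
    sparse random connectivity at a fixed connection probability, recurrence,
    thresholded (ReLU) activation, and Dale's principle (each hidden node
    exclusively excitatory or inhibitory, enforced throughout training).
    Networks are trained by backpropagation through time with the Adam
    optimiser under mask and sign-projection constraints, in time-limited
    (single epoch) and data-limited (reduced training set) regimes.
    Representation analyses quantify activation sparsity, pairwise mutual
    information between hidden nodes (Kraskov k-nearest-neighbour estimator),
    correlation structure at initialization, robustness to test-time dropout,
    and the training delay induced by excitation-inhibition imbalance.
    Includes a synthetic generator of row-scanned image-like sequence
    classification tasks and experiment-grid orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
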