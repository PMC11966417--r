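# Shared fixtures: tiny tasks and networks built in code at test time.

tiny_task <- function(n_train = 100L, n_test = 60L, seed = 7L,
                      seq_len = 8L, input_dim = 6L, n_classes = 4L) {
  make_task(synthetic_task_spec(
    n_classes = n_classes, seq_len = seq_len, input_dim = input_dim,
    n_train = n_train, n_test = n_test, seed = seed
  ))
}

tiny_network <- function(n_hidden = 32L, p = 0.5, input_dim = 6L,
                         n_classes = 4L, seed = 1L, ...) {
  spec <- connectivity_spec(n_hidden, p, seed = seed, ...)
  build_network(spec, input_dim = input_dim, n_classes = n_classes)
}

# Plug-in (exhaustive histogram) mutual information for discrete samples,
# in nats: the independent oracle for the k-NN estimator.
histogram_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  sum(tab * log(tab / outer(px, py)), na.rm = TRUE)
}
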