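# Forward computation for recurrent and feedforward-control networks.
# Pure functions of (params, input); training never mutates in place.

apply_activation <- function(x, kind) {
  if (kind == "relu") {
    x[x < 0] <- 0
    x
  } else {
    tanh(x)
  }
}

as_sequence_batch <- function(sequences) {
  if (is.matrix(sequences)) {
    # single T x d sequence
    array(sequences, dim = c(1L, nrow(sequences), ncol(sequences)))
  } else if (is.array(sequences) && length(dim(sequences)) == 3L) {
    sequences
  } else {
    stop_param("`sequences` must be a T x d matrix or an n x T x d array")
  }
}

#' Forward pass of a recurrent network
#'
#' Unrolls the recurrence `h_t = phi(x_t W_in + h_{t-1} W_hh)` from
#' `h_0 = 0` over the T timesteps of each input sequence and reads out
#' linearly from the final hidden state: `logits = h_T W_out`. Weights at
#' masked positions are exactly zero and therefore contribute nothing.
#'
#' @param params a `network_params` object (recurrent architecture).
#' @param sequences a single T x d matrix or an n x T x d array.
#' @param return_trajectory also return the full hidden trajectory (a list
#'   of n x N matrices, one per timestep), needed for backpropagation
#'   through time.
#' @return list with `hidden` (n x N final-timestep activations), `logits`
#'   (n x n_classes), and optionally `trajectory`.
#' @export
forward_recurrent <- function(params, sequences, return_trajectory = FALSE) {
  stopifnot(inherits(params, "network_params"))
  if (params$architecture != "recurrent") {
    stop_param("`params` is not a recurrent network")
  }
  x <- as_sequence_batch(sequences)
  d <- dim(x)
  if (d[3] != nrow(params$w_in)) {
    stop_param("input dimension ", d[3], " does not match w_in (",
               nrow(params$w_in), ")")
  }
  n <- d[1]
  n_hidden <- ncol(params$w_in)
  h <- matrix(0, n, n_hidden)
  traj <- if (return_trajectory) vector("list", d[2])
  b_h <- params$b_h
  for (t in seq_len(d[2])) {
    xt <- matrix(x[, t, ], nrow = n)
    pre <- xt %*% params$w_in + h %*% params$w_hh
    if (!is.null(b_h)) pre <- sweep(pre, 2L, b_h, "+")
    h <- apply_activation(pre, params$activation)
    if (return_trajectory) traj[[t]] <- h
  }
  logits <- h %*% params$w_out
  if (!is.null(params$b_out)) logits <- sweep(logits, 2L, params$b_out, "+")
  out <- list(hidden = h, logits = logits)
  if (return_trajectory) out$trajectory <- traj
  out
}

#' Forward pass of the two-layer feedforward control
#'
#' The control architecture for isolating the role of recurrence: the hidden
#' nodes are split into two layers, the whole input is presented at once as
#' a flat vector, and the connection probability is applied to the
#' inter-layer weights. `layer1 = phi(x W_in)`, `layer2 = phi(layer1 W_12)`,
#' `logits = layer2 W_out`.
#'
#' @param params a `network_params` object with feedforward architecture
#'   (`w_hh` holds the masked inter-layer weights W_12).
#' @param flat_input numeric vector (one sample) or n x D matrix.
#' @return list with `hidden` (final hidden layer) and `logits`.
#' @export
forward_feedforward <- function(params, flat_input) {
  stopifnot(inherits(params, "network_params"))
  if (params$architecture != "feedforward_2layer") {
    stop_param("`params` is not a feedforward network")
  }
  x <- if (is.matrix(flat_input)) flat_input else matrix(flat_input, nrow = 1L)
  if (ncol(x) != nrow(params$w_in)) {
    stop_param("input length ", ncol(x), " does not match w_in (",
               nrow(params$w_in), ")")
  }
  l1 <- apply_activation(x %*% params$w_in, params$activation)
  l2 <- apply_activation(l1 %*% params$w_hh, params$activation)
  logits <- l2 %*% params$w_out
  list(hidden = l2, logits = logits, layer1 = l1)
}

forward_network <- function(params, dataset_or_x, return_trajectory = FALSE) {
  if (params$architecture == "recurrent") {
    x <- if (inherits(dataset_or_x, "sequence_dataset")) {
      dataset_or_x$sequences
    } else {
      dataset_or_x
    }
    forward_recurrent(params, x, return_trajectory = return_trajectory)
  } else {
    x <- if (inherits(dataset_or_x, "sequence_dataset")) {
      flatten_sequences(dataset_or_x)
    } else {
      dataset_or_x
    }
    forward_feedforward(params, x)
  }
}

#' Predicted classes from logits
#'
#' Argmax over classes with ties broken toward the lowest class index;
#' classes are zero-based throughout the package.
#'
#' @param logits n x n_classes matrix (or a single logit vector).
#' @return integer vector of zero-based class predictions.
#' @export
#' @examples
#' predict_classes(rbind(c(0.1, 0.9), c(0.5, 0.5)))  # 1, then 0 (tie rule)
predict_classes <- function(logits) {
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1L)
  if (any(is.na(logits)) || any(!is.finite(logits))) {
    stop_param("logits contain NaN/Inf")
  }
  max.col(logits, ties.method = "first") - 1L
}

#' Classification accuracy of a network on a dataset
#'
#' @param params a `network_params` object.
#' @param dataset a [sequence_dataset()].
#' @param batch_size internal evaluation batch size (memory control only;
#'   the result is independent of it).
#' @return accuracy in \[0, 1\].
#' @export
evaluate_accuracy <- function(params, dataset, batch_size = 500L) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  n <- n_samples(dataset)
  flat <- if (params$architecture != "recurrent") flatten_sequences(dataset)
  correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out <- if (is.null(flat)) {
      forward_recurrent(params, dataset$sequences[idx, , , drop = FALSE])
    } else {
      forward_feedforward(params, flat[idx, , drop = FALSE])
    }
    correct <- correct + sum(predict_classes(out$logits) == dataset$labels[idx])
  }
  correct / n
}

#' Record final-timestep hidden activations
#'
#' The activation values each hidden node sends to the output layer — the
#' substrate of all representation analyses (activation sparsity, mutual
#' information, correlations, dropout).
#'
#' @param params a `network_params` object.
#' @param dataset a [sequence_dataset()].
#' @param batch_size internal batch size.
#' @return an n_samples x N matrix of final-timestep activations.
#' @export
record_activations <- function(params, dataset, batch_size = 500L) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  n <- n_samples(dataset)
  flat <- if (params$architecture != "recurrent") flatten_sequences(dataset)
  n_hidden <- ncol(params$w_hh)
  out <- matrix(0, n, n_hidden)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- if (is.null(flat)) {
      forward_recurrent(params, dataset$sequences[idx, , , drop = FALSE])$hidden
    } else {
      forward_feedforward(params, flat[idx, , drop = FALSE])$hidden
    }
  }
  out
}
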