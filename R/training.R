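#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param optimizer only `"adam"` is provided (beta1 = 0.9, beta2 = 0.999,
#'   eps = 1e-8).
#' @param loss only `"cross_entropy"` (softmax cross-entropy on the linear
#'   readout, targets one-hot).
#' @param batch_size minibatch size (default 100).
#' @param max_epochs maximum number of passes over the training data.
#' @param early_stop_patience stop when test accuracy has not improved for
#'   this many consecutive epochs (`NULL` = no early stopping).
#' @param mode `"standard"` keeps masked hidden-layer weights at exactly
#'   zero after every optimizer step; `"sparse_to_dense"` uses the mask only
#'   at initialization and lets zero-initialized weights become nonzero
#'   during training.
#' @param record_gradients record the mean absolute hidden-layer gradient
#'   (over unmasked entries) per epoch.
#' @param shuffle reshuffle the training set every epoch (seeded).
#' @param stop_at_accuracy optionally stop as soon as test accuracy exceeds
#'   this value (useful when only the first crossing of chance level is of
#'   interest, e.g. for training-delay measurements).
#' @param seed integer seed controlling shuffling order.
#' @return an object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001,
                            optimizer = "adam",
                            loss = "cross_entropy",
                            batch_size = 100L,
                            max_epochs = 10L,
                            early_stop_patience = NULL,
                            mode = c("standard", "sparse_to_dense"),
                            record_gradients = FALSE,
                            shuffle = TRUE,
                            stop_at_accuracy = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "cross_entropy")
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop_param("`learning_rate` must be positive")
  }
  if (!is_count(batch_size)) stop_param("`batch_size` must be a positive integer")
  if (!is_count(max_epochs)) stop_param("`max_epochs` must be a positive integer")
  if (!is.null(early_stop_patience) && !is_count(early_stop_patience)) {
    stop_param("`early_stop_patience` must be >= 1 when set")
  }
  structure(
    list(
      learning_rate = learning_rate,
      optimizer = optimizer,
      loss = loss,
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      early_stop_patience = early_stop_patience,
      mode = mode,
      record_gradients = isTRUE(record_gradients),
      shuffle = isTRUE(shuffle),
      stop_at_accuracy = stop_at_accuracy,
      seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

# Numerically stable softmax cross-entropy.
# Returns mean loss and the gradient wrt the logits (already divided by n).
softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  m <- apply(logits, 1L, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  picked <- z[cbind(seq_len(n), labels + 1L)]
  loss <- mean(lse - picked)
  p <- exp(z - lse)
  p[cbind(seq_len(n), labels + 1L)] <- p[cbind(seq_len(n), labels + 1L)] - 1
  list(loss = loss, dlogits = p / n)
}

activation_grad <- function(h, kind) {
  if (kind == "relu") {
    (h > 0) * 1
  } else {
    1 - h * h
  }
}

#' Loss and gradients of a network on one minibatch
#'
#' Backpropagation (through time, for recurrent networks) of the softmax
#' cross-entropy loss. Gradients are returned raw, i.e. including positions
#' that the mask will afterwards project back to zero; training applies the
#' mask/Dale projections after the optimizer step.
#'
#' @param params a `network_params` object.
#' @param x input batch: n x T x d array (recurrent) or n x D matrix
#'   (feedforward).
#' @param labels zero-based integer labels of the batch.
#' @return list with `loss` and `grads` (matching names `w_in`, `w_hh`,
#'   `w_out`, plus `b_h`/`b_out` when biases are enabled).
#' @export
network_gradients <- function(params, x, labels) {
  if (params$architecture == "recurrent") {
    x <- as_sequence_batch(x)
    n <- dim(x)[1]
    T_len <- dim(x)[2]
    fwd <- forward_recurrent(params, x, return_trajectory = TRUE)
    ce <- softmax_xent(fwd$logits, labels)
    h_final <- fwd$trajectory[[T_len]]
    g_out <- crossprod(h_final, ce$dlogits)
    g_in <- matrix(0, nrow(params$w_in), ncol(params$w_in))
    g_hh <- matrix(0, nrow(params$w_hh), ncol(params$w_hh))
    g_bh <- if (!is.null(params$b_h)) rep(0, length(params$b_h))
    dh <- ce$dlogits %*% t(params$w_out)
    for (t in T_len:1) {
      da <- dh * activation_grad(fwd$trajectory[[t]], params$activation)
      xt <- matrix(x[, t, ], nrow = n)
      g_in <- g_in + crossprod(xt, da)
      h_prev <- if (t > 1L) fwd$trajectory[[t - 1L]] else matrix(0, n, ncol(g_hh))
      if (t > 1L) g_hh <- g_hh + crossprod(h_prev, da)
      if (!is.null(g_bh)) g_bh <- g_bh + colSums(da)
      dh <- da %*% t(params$w_hh)
    }
    grads <- list(w_in = g_in, w_hh = g_hh, w_out = g_out)
    if (!is.null(g_bh)) {
      grads$b_h <- g_bh
      grads$b_out <- colSums(ce$dlogits)
    }
    list(loss = ce$loss, grads = grads)
  } else {
    if (!is.matrix(x)) stop_param("feedforward networks take an n x D matrix")
    fwd <- forward_feedforward(params, x)
    ce <- softmax_xent(fwd$logits, labels)
    d2 <- (ce$dlogits %*% t(params$w_out)) *
      activation_grad(fwd$hidden, params$activation)
    d1 <- (d2 %*% t(params$w_hh)) *
      activation_grad(fwd$layer1, params$activation)
    list(
      loss = ce$loss,
      grads = list(
        w_in = crossprod(x, d1),
        w_hh = crossprod(fwd$layer1, d2),
        w_out = crossprod(fwd$hidden, ce$dlogits)
      )
    )
  }
}

adam_init <- function(params, names) {
  lapply(stats::setNames(names, names), function(nm) {
    list(m = params[[nm]] * 0, v = params[[nm]] * 0)
  })
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(state)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g * g
    m_hat <- state[[nm]]$m / (1 - beta1^t)
    v_hat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(params = params, state = state)
}

# Projections applied after every optimizer step, mask first, then Dale.
# Dale: any outgoing weight of hidden node i whose sign flipped relative to
# signs[i] is set to exactly zero (it remains trainable thereafter).
project_constraints <- function(params, mask, signs, mode) {
  n_zeroed <- 0L
  if (mode == "standard") {
    params$w_hh <- params$w_hh * mask
  }
  if (!is.null(signs)) {
    viol_hh <- (params$w_hh * signs) < 0
    n_zeroed <- sum(viol_hh)
    if (n_zeroed > 0L) params$w_hh[viol_hh] <- 0
    viol_out <- (params$w_out * signs) < 0
    n_zeroed <- n_zeroed + sum(viol_out)
    if (any(viol_out)) params$w_out[viol_out] <- 0
  }
  list(params = params, n_zeroed = n_zeroed)
}

#' Train a network by backpropagation under mask and Dale constraints
#'
#' Minibatch Adam on the softmax cross-entropy loss. After every optimizer
#' step, masked hidden-layer weights are reset to exactly zero (standard
#' mode), and under Dale's principle any outgoing weight whose update would
#' reverse the sign of its node is set to zero instead (and remains
#' trainable). Test accuracy is evaluated on the full test split after
#' every epoch.
#'
#' @param params initial `network_params` (see [build_network()]).
#' @param train_set,test_set [sequence_dataset()] splits.
#' @param config a [training_config()].
#' @param mask,signs connectivity mask and Dale sign vector; default to the
#'   ones stored in `params`.
#' @return list with `params` (trained weights) and `trace`, a data.frame
#'   with one row per epoch: `epoch`, `test_accuracy`, `train_loss`,
#'   `mean_abs_gradient_hh` (NA unless `record_gradients`), sign-change
#'   counts of the hidden-layer weights over the epoch (`pos_to_neg`,
#'   `neg_to_pos`) and `zeroed_by_dale` (0 for non-Dale networks).
#' @export
train_network <- function(params, train_set, test_set, config,
                          mask = params$mask, signs = params$signs) {
  stopifnot(inherits(params, "network_params"),
            inherits(train_set, "sequence_dataset"),
            inherits(test_set, "sequence_dataset"),
            inherits(config, "training_config"))
  if (!is.null(signs) && length(signs) != nrow(params$w_hh)) {
    stop_param("`signs` length must equal the number of hidden nodes")
  }
  n_train <- n_samples(train_set)
  tensors <- intersect(c("w_in", "w_hh", "w_out", "b_h", "b_out"), names(params))
  tensors <- tensors[!vapply(params[tensors], is.null, logical(1))]
  state <- adam_init(params, tensors)
  flat <- if (params$architecture != "recurrent") flatten_sequences(train_set)
  unmasked <- if (config$mode == "standard") sum(mask) else length(mask)

  trace <- data.frame(
    epoch = integer(), test_accuracy = numeric(), train_loss = numeric(),
    mean_abs_gradient_hh = numeric(), pos_to_neg = integer(),
    neg_to_pos = integer(), zeroed_by_dale = integer()
  )
  step <- 0L
  best_acc <- -Inf
  stall <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      order_idx <- if (config$shuffle) sample.int(n_train) else seq_len(n_train)
      w_hh_start <- params$w_hh
      epoch_loss <- 0
      epoch_grad <- 0
      epoch_zeroed <- 0L
      n_batches <- 0L
      for (start in seq(1L, n_train, by = config$batch_size)) {
        idx <- order_idx[start:min(start + config$batch_size - 1L, n_train)]
        xb <- if (is.null(flat)) {
          train_set$sequences[idx, , , drop = FALSE]
        } else {
          flat[idx, , drop = FALSE]
        }
        gb <- network_gradients(params, xb, train_set$labels[idx])
        if (!is.finite(gb$loss)) {
          stop_param("training aborted: non-finite loss at epoch ", epoch,
                     " (learning rate too high or activations diverged)")
        }
        step <- step + 1L
        upd <- adam_step(params, gb$grads, state, config$learning_rate, step)
        params <- upd$params
        state <- upd$state
        proj <- project_constraints(params, mask, signs, config$mode)
        params <- proj$params
        epoch_zeroed <- epoch_zeroed + proj$n_zeroed
        epoch_loss <- epoch_loss + gb$loss
        if (config$record_gradients && unmasked > 0) {
          g <- if (config$mode == "standard") gb$grads$w_hh * mask else gb$grads$w_hh
          epoch_grad <- epoch_grad + sum(abs(g)) / unmasked
        }
        n_batches <- n_batches + 1L
      }
      sc <- sign_change_stats(w_hh_start, params$w_hh)
      acc <- evaluate_accuracy(params, test_set)
      trace[nrow(trace) + 1L, ] <- list(
        epoch = epoch,
        test_accuracy = acc,
        train_loss = epoch_loss / n_batches,
        mean_abs_gradient_hh = if (config$record_gradients) {
          epoch_grad / n_batches
        } else NA_real_,
        pos_to_neg = sc$pos_to_neg,
        neg_to_pos = sc$neg_to_pos,
        zeroed_by_dale = epoch_zeroed
      )
      if (!is.null(config$stop_at_accuracy) && acc > config$stop_at_accuracy) {
        break
      }
      if (!is.null(config$early_stop_patience)) {
        if (acc > best_acc) {
          best_acc <- acc
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$early_stop_patience) break
        }
      }
    }
  })
  list(params = params, trace = trace)
}

#' Test accuracy after a single training epoch
#'
#' The time-limited-learning metric: performance on the test set after the
#' network has seen each training example exactly once.
#'
#' @inheritParams train_network
#' @return accuracy in \[0, 1\].
#' @export
single_epoch_accuracy <- function(params, train_set, test_set, config,
                                  mask = params$mask, signs = params$signs) {
  config$max_epochs <- 1L
  config$early_stop_patience <- NULL
  config$stop_at_accuracy <- NULL
  fit <- train_network(params, train_set, test_set, config,
                       mask = mask, signs = signs)
  fit$trace$test_accuracy[1L]
}

#' Sign-change statistics between two weight snapshots
#'
#' Elementwise counts of sign transitions and magnitude increases between a
#' before and an after weight matrix, used to characterize how sparse
#' representations form during training (negative weights tend to grow in
#' magnitude and positive weights to turn negative more often than the
#' reverse).
#'
#' @param w_before,w_after numeric matrices of identical shape.
#' @return list of counts: `pos_to_neg`, `neg_to_pos`,
#'   `pos_magnitude_increase`, `neg_magnitude_increase`.
#' @export
sign_change_stats <- function(w_before, w_after) {
  if (!identical(dim(w_before), dim(w_after))) {
    stop_param("`w_before` and `w_after` must have the same shape")
  }
  list(
    pos_to_neg = sum(w_before > 0 & w_after < 0),
    neg_to_pos = sum(w_before < 0 & w_after > 0),
    pos_magnitude_increase = sum(w_before > 0 & w_after > w_before),
    neg_magnitude_increase = sum(w_before < 0 & w_after < w_before)
  )
}

#' Mean absolute gradient over unmasked hidden-layer entries
#'
#' @param grad_hh gradient matrix for the hidden-layer weights.
#' @param mask optional 0/1 mask; when supplied, only unmasked entries are
#'   averaged. Returns `NA` if no entries are admissible.
#' @return mean absolute gradient (a scalar), or `NA`.
#' @export
record_gradient_magnitude <- function(grad_hh, mask = NULL) {
  if (is.null(mask)) {
    return(mean(abs(grad_hh)))
  }
  if (!identical(dim(grad_hh), dim(mask))) {
    stop_param("`grad_hh` and `mask` must have the same shape")
  }
  k <- sum(mask)
  if (k == 0) {
    return(NA_real_)
  }
  sum(abs(grad_hh * mask)) / k
}
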