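# Representation and training-dynamics analyses: activation sparsity,
# pairwise mutual information, initialization correlations, test-time
# dropout robustness, and the training-delay metric.

#' Fraction of hidden nodes with nonzero output per sample
#'
#' For every input, the fraction of hidden-layer nodes whose final-timestep
#' activation is strictly positive — i.e. how many nodes actually send a
#' signal to the readout. Distributed codes have high fractions, winner-
#' take-all-like codes low ones.
#'
#' @param record n_samples x N activation matrix (see [record_activations()]).
#' @return list with `per_sample` (length-n vector of fractions), `mean`
#'   and `sd`.
#' @export
nonzero_fraction <- function(record) {
  if (!is.matrix(record) || nrow(record) == 0L || ncol(record) == 0L) {
    stop_param("`record` must be a non-empty activation matrix")
  }
  frac <- rowMeans(record > 0)
  list(per_sample = frac, mean = mean(frac), sd = stats::sd(frac))
}

#' Histogram and moments of activation magnitudes
#'
#' Summarizes the distribution of the (nonzero) activation values hidden
#' nodes send to the output layer.
#'
#' @param record n_samples x N activation matrix.
#' @param breaks passed to [graphics::hist()]'s binning via [base::cut()];
#'   either a count or a vector of break points.
#' @return list with `histogram` (data.frame of bin mids and counts; empty
#'   when there are no nonzero activations), `mean`, `sd` (moments of the
#'   nonzero activations), `n_nonzero` and `n_total`.
#' @export
activation_magnitude_summary <- function(record, breaks = 50L) {
  if (!is.matrix(record) || length(record) == 0L) {
    stop_param("`record` must be a non-empty activation matrix")
  }
  vals <- record[record != 0]
  if (length(vals) == 0L) {
    return(list(
      histogram = data.frame(mid = numeric(), count = integer()),
      mean = NA_real_, sd = NA_real_, n_nonzero = 0L, n_total = length(record)
    ))
  }
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  list(
    histogram = data.frame(mid = h$mids, count = h$counts),
    mean = mean(vals),
    sd = stats::sd(vals),
    n_nonzero = length(vals),
    n_total = length(record)
  )
}

# Sample `n_pairs` distinct unordered node pairs (i < j) uniformly at
# random from the choose(n, 2) possibilities, without replacement. Small n:
# enumerate and subsample; large n: rejection sampling with deduplication.
sample_node_pairs <- function(n, n_pairs) {
  total <- n * (n - 1) / 2
  if (n_pairs >= total || n <= 1024L) {
    idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    pairs <- cbind(i = idx[, "row"], j = idx[, "col"])
    if (n_pairs < total) {
      pairs <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
    }
    return(pairs)
  }
  i <- integer(0)
  j <- integer(0)
  while (length(i) < n_pairs) {
    need <- n_pairs - length(i)
    a <- sample.int(n, 2L * need, replace = TRUE)
    b <- sample.int(n, 2L * need, replace = TRUE)
    ok <- a != b
    lo <- pmin(a, b)[ok]
    hi <- pmax(a, b)[ok]
    i <- c(i, lo)
    j <- c(j, hi)
    keep <- !duplicated(i * (n + 1) + j)
    i <- i[keep]
    j <- j[keep]
  }
  cbind(i = i[seq_len(n_pairs)], j = j[seq_len(n_pairs)])
}

#' Kraskov k-nearest-neighbour mutual information between two samples
#'
#' Continuous MI estimate (in nats) between two paired samples, using the
#' first Kraskov estimator: `psi(k) + psi(n) - <psi(nx + 1) + psi(ny + 1)>`
#' with Chebyshev balls in the joint space. A vanishing-amplitude uniform
#' jitter (seedable via the caller's RNG) breaks ties so the estimator is
#' well-defined on discretized data. If either input has zero variance the
#' MI is defined as 0.
#'
#' @param x,y numeric vectors of equal length (n >= k + 1).
#' @param k number of neighbours (default 3).
#' @return MI estimate in nats (may be slightly negative; see
#'   [pairwise_mutual_information()] for the clipped distribution form).
#' @export
knn_mutual_information <- function(x, y, k = 3L) {
  n <- length(x)
  if (length(y) != n) stop_param("`x` and `y` must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(0)
  }
  if (n < k + 1L) stop_param("need at least k + 1 observations")
  # tie-breaking jitter, tiny relative to the data scale
  x <- x + runif(n, -1, 1) * 1e-10 * max(stats::sd(x), 1e-100)
  y <- y + runif(n, -1, 1) * 1e-10 * max(stats::sd(y), 1e-100)
  eps <- chebyshev_knn_dist(x, y, as.integer(k))
  ox <- sort(x)
  oy <- sort(y)
  # strict counts: #{j != i : |x_j - x_i| < eps_i}
  nx <- findInterval(x + eps, ox, left.open = TRUE) -
    findInterval(x - eps, ox) - 1L
  ny <- findInterval(y + eps, oy, left.open = TRUE) -
    findInterval(y - eps, oy) - 1L
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

#' Mutual information distribution over random hidden-node pairs
#'
#' Estimates the continuous mutual information (nats, Kraskov k-NN
#' estimator) between the responses of randomly sampled pairs of hidden
#' nodes across a whole dataset. High pairwise MI across many node pairs
#' indicates a distributed code in which information is shared over the
#' population.
#'
#' @param record n_samples x N activation matrix.
#' @param n_pairs number of distinct node pairs to sample (without
#'   replacement; capped at choose(N, 2)).
#' @param k_neighbors k for the k-NN estimator (default 3).
#' @param seed integer seed for pair sampling and tie-breaking jitter.
#' @return list with `mi` (per-pair estimates, negatives clipped to 0),
#'   `pairs` (the sampled index pairs), `mean`, `sd` and `n_clipped` (how
#'   many raw estimates were negative before clipping).
#' @export
pairwise_mutual_information <- function(record, n_pairs = 10000L,
                                        k_neighbors = 3L, seed = 1L) {
  if (!is.matrix(record) || nrow(record) < k_neighbors + 1L) {
    stop_param("`record` must be a matrix with more than `k_neighbors` rows")
  }
  if (!is_count(n_pairs)) stop_param("`n_pairs` must be >= 1")
  with_seed(seed, {
    pairs <- sample_node_pairs(ncol(record), n_pairs)
    mi <- vapply(seq_len(nrow(pairs)), function(r) {
      knn_mutual_information(record[, pairs[r, 1L]], record[, pairs[r, 2L]],
                             k = k_neighbors)
    }, numeric(1))
    n_clipped <- sum(mi < 0)
    mi[mi < 0] <- 0
    list(
      mi = mi, pairs = pairs,
      mean = mean(mi), sd = stats::sd(mi),
      n_clipped = n_clipped
    )
  })
}

#' Pairwise activation correlations of an untrained network
#'
#' Pearson correlation coefficients between the final-timestep activation
#' vectors of hidden-node pairs in response to a probe set, computed before
#' any training. Densely connected networks with a cortex-like
#' excitation-inhibition imbalance show highly correlated (near-redundant)
#' activations at initialization; sparse connectivity decorrelates them.
#'
#' @param params an untrained `network_params` object.
#' @param probe_set a [sequence_dataset()] of probe inputs (see
#'   [make_probe_inputs()]).
#' @param n_pairs number of node pairs to sample when all `choose(N, 2)`
#'   pairs are infeasible.
#' @param seed integer seed for pair subsampling.
#' @return list with `r` (per-pair Pearson coefficients), `mean_abs_r`,
#'   `mean_r`, and `n_constant` (nodes with constant activation, excluded
#'   from pairing).
#' @export
init_correlations <- function(params, probe_set, n_pairs = 10000L, seed = 1L) {
  record <- record_activations(params, probe_set)
  activation_correlations(record, n_pairs = n_pairs, seed = seed)
}

#' @rdname init_correlations
#' @param record n_samples x N activation matrix (alternative entry point
#'   when activations are already recorded).
#' @export
activation_correlations <- function(record, n_pairs = 10000L, seed = 1L) {
  sds <- apply(record, 2L, stats::sd)
  varying <- which(sds > 0)
  n_constant <- ncol(record) - length(varying)
  if (length(varying) < 2L) {
    stop_param("fewer than 2 hidden nodes with varying activation")
  }
  record <- record[, varying, drop = FALSE]
  with_seed(seed, {
    pairs <- sample_node_pairs(ncol(record), n_pairs)
    r <- vapply(seq_len(nrow(pairs)), function(k) {
      stats::cor(record[, pairs[k, 1L]], record[, pairs[k, 2L]])
    }, numeric(1))
    list(
      r = r,
      mean_abs_r = mean(abs(r)),
      mean_r = mean(r),
      n_constant = n_constant
    )
  })
}

#' Test-time dropout robustness
#'
#' For every test sample an independent random subset of hidden nodes has
#' its final-timestep output set to zero before the readout (no rescaling
#' of the survivors), probing how much the classification relies on
#' individual nodes. The dropped subset is resampled per sample, and the
#' whole evaluation repeated `n_repeats` times.
#'
#' @param params a `network_params` object.
#' @param test_set a [sequence_dataset()].
#' @param fractions dropout fractions in \[0, 1\]; `round(fraction * N)`
#'   nodes are dropped per sample.
#' @param n_repeats independent repetitions averaged per fraction.
#' @param seed integer seed.
#' @param record optional precomputed activation matrix for `test_set`
#'   (avoids recomputing the forward pass).
#' @return data.frame with columns `fraction`, `accuracy` (mean over
#'   repeats) and `sd_accuracy`.
#' @export
dropout_robustness <- function(params, test_set, fractions,
                               n_repeats = 1L, seed = 1L, record = NULL) {
  if (any(fractions < 0 | fractions > 1)) {
    stop_param("`fractions` must lie in [0, 1]")
  }
  if (is.null(record)) record <- record_activations(params, test_set)
  n <- nrow(record)
  n_hidden <- ncol(record)
  labels <- test_set$labels
  w_out <- params$w_out
  b_out <- params$b_out
  acc_of <- function(h) {
    logits <- h %*% w_out
    if (!is.null(b_out)) logits <- sweep(logits, 2L, b_out, "+")
    mean(predict_classes(logits) == labels)
  }
  with_seed(seed, {
    res <- lapply(fractions, function(f) {
      n_drop <- round(f * n_hidden)
      accs <- vapply(seq_len(n_repeats), function(rep) {
        if (n_drop == 0L) {
          return(acc_of(record))  # bit-exact undropped evaluation
        }
        h <- record
        for (s in seq_len(n)) {
          h[s, sample.int(n_hidden, n_drop)] <- 0
        }
        acc_of(h)
      }, numeric(1))
      data.frame(fraction = f, accuracy = mean(accs),
                 sd_accuracy = if (n_repeats > 1L) stats::sd(accs) else NA_real_)
    })
    do.call(rbind, res)
  })
}

#' Training delay: epochs spent at chance level
#'
#' Dale-constrained dense networks can spend many epochs at chance accuracy
#' before learning starts. The delay is the number of epochs before test
#' accuracy first exceeds `1/n_classes + margin`: an immediate learner has
#' delay 0, and a network whose trace never crosses gets the sentinel
#' `"never"` (`delay_epochs = Inf`).
#'
#' @param trace a training trace data.frame (from [train_network()]) or a
#'   numeric vector of per-epoch test accuracies.
#' @param n_classes number of classes (chance level = 1/n_classes).
#' @param margin required excess over chance (default 0.02).
#' @param sustained require two consecutive epochs above threshold.
#' @return an object of class `delay_result`: list with `delay_epochs`
#'   (epochs before the first crossing; `Inf` when never),
#'   `first_above_chance` (1-based epoch index of the first crossing, `NA`
#'   when never), `crossed`, `chance_level` and `margin`.
#' @export
#' @examples
#' training_delay(c(0.10, 0.11, 0.35, 0.60), n_classes = 10)
training_delay <- function(trace, n_classes, margin = 0.02,
                           sustained = FALSE) {
  acc <- if (is.data.frame(trace)) trace$test_accuracy else as.numeric(trace)
  if (length(acc) == 0L) stop_param("`trace` is empty")
  if (margin < 0) stop_param("`margin` must be >= 0")
  chance <- 1 / n_classes
  above <- acc > chance + margin
  if (sustained && length(above) > 1L) {
    above <- above & c(above[-1L], FALSE)
  }
  first <- which(above)
  crossed <- length(first) > 0L
  structure(
    list(
      delay_epochs = if (crossed) first[1L] - 1L else Inf,
      first_above_chance = if (crossed) first[1L] else NA_integer_,
      crossed = crossed,
      chance_level = chance,
      margin = margin
    ),
    class = "delay_result"
  )
}

#' @export
print.delay_result <- function(x, ...) {
  if (x$crossed) {
    cat(sprintf("<delay_result> %d epoch(s) at chance before crossing %.3f (chance %.3f + margin %.3f)\n",
                x$delay_epochs, x$chance_level + x$margin, x$chance_level, x$margin))
  } else {
    cat(sprintf("<delay_result> never crossed %.3f (chance %.3f + margin %.3f)\n",
                x$chance_level + x$margin, x$chance_level, x$margin))
  }
  invisible(x)
}
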