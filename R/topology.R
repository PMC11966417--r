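#' Describe one network architecture draw
#'
#' A connectivity spec collects every knob that defines a single network
#' architecture: hidden-layer size, connection probability between hidden
#' nodes, recurrent vs. two-layer feedforward control, activation function,
#' and the Dale-law settings (fixed excitatory/inhibitory node identities).
#'
#' @param n_hidden number of hidden-layer nodes (N), at least 2.
#' @param connection_probability probability p in \[0, 1\] that a directed
#'   trainable edge exists between two distinct hidden nodes. Equals the
#'   expected network density `E / (N (N - 1))`.
#' @param architecture `"recurrent"` (single recurrently connected hidden
#'   layer, sequence input) or `"feedforward_2layer"` (nodes split into two
#'   hidden layers with the connection probability applied to the
#'   inter-layer weights, flattened input).
#' @param activation `"relu"` or `"tanh"`.
#' @param dale if `TRUE`, every hidden node is fixed as excitatory (+1) or
#'   inhibitory (-1) and all its outgoing weights keep that sign for the
#'   whole of training.
#' @param inhibitory_fraction fraction of inhibitory nodes under Dale's
#'   principle; the default 0.115 is the proportion of inhibitory neurons
#'   reported for sensory cortex. Ignored when `dale = FALSE`.
#' @param inhibitory_scale multiplier applied to the initial magnitudes of
#'   inhibitory outgoing weights (default 1; 10 reproduces the ten-fold
#'   inhibitory-strengthening manipulation).
#' @param weight_init_bound b > 0: initial weights are uniform on (-b, b)
#'   (non-Dale) or have magnitude uniform on (0, b) (Dale). Default 0.001.
#' @param use_bias add trainable bias vectors to the hidden and output
#'   layers (default `FALSE`; biases are exempt from the Dale constraint).
#' @param io_init initialization scheme for the input and readout weights:
#'   `"uniform_bound"` (same uniform(-b, b) scheme as the hidden layer,
#'   default) or `"kaiming"` (uniform on +/- sqrt(1/fan_in), the usual
#'   framework default) for sensitivity checks.
#' @param seed integer seed making mask, sign and weight draws reproducible.
#'
#' @return an object of class `connectivity_spec`.
#' @seealso [build_network()], [sample_mask()], [assign_ei()], [init_weights()]
#' @export
#' @examples
#' connectivity_spec(256, 0.1, dale = TRUE, seed = 1)
connectivity_spec <- function(n_hidden,
                              connection_probability,
                              architecture = c("recurrent", "feedforward_2layer"),
                              activation = c("relu", "tanh"),
                              dale = FALSE,
                              inhibitory_fraction = 0.115,
                              inhibitory_scale = 1,
                              weight_init_bound = 0.001,
                              use_bias = FALSE,
                              io_init = c("uniform_bound", "kaiming"),
                              seed = 1L) {
  architecture <- match.arg(architecture)
  activation <- match.arg(activation)
  io_init <- match.arg(io_init)
  if (!is_count(n_hidden, min = 2L)) {
    stop_param("`n_hidden` must be a single integer >= 2")
  }
  if (!is_prob(connection_probability)) {
    stop_param("`connection_probability` must be in [0, 1]")
  }
  if (!is_prob(inhibitory_fraction)) {
    stop_param("`inhibitory_fraction` must be in [0, 1]")
  }
  if (!is.numeric(inhibitory_scale) || inhibitory_scale <= 0) {
    stop_param("`inhibitory_scale` must be positive")
  }
  if (!is.numeric(weight_init_bound) || weight_init_bound <= 0) {
    stop_param("`weight_init_bound` must be positive")
  }
  if (dale && architecture != "recurrent") {
    stop_param("Dale's principle is only supported for recurrent networks")
  }
  structure(
    list(
      n_hidden = as.integer(n_hidden),
      connection_probability = connection_probability,
      architecture = architecture,
      activation = activation,
      dale = isTRUE(dale),
      inhibitory_fraction = inhibitory_fraction,
      inhibitory_scale = inhibitory_scale,
      weight_init_bound = weight_init_bound,
      use_bias = isTRUE(use_bias),
      io_init = io_init,
      seed = as.integer(seed)
    ),
    class = "connectivity_spec"
  )
}

#' @export
print.connectivity_spec <- function(x, ...) {
  cat(sprintf(
    "<connectivity_spec> N=%d, p=%g, %s, %s%s, seed=%d\n",
    x$n_hidden, x$connection_probability, x$architecture, x$activation,
    if (x$dale) {
      sprintf(", Dale (%.1f%% inhibitory, scale %g)",
              100 * x$inhibitory_fraction, x$inhibitory_scale)
    } else "",
    x$seed
  ))
  invisible(x)
}

# Unseeded mask draw; callers own the RNG state.
draw_mask <- function(n_pre, n_post, p, recurrent) {
  m <- matrix(as.numeric(runif(n_pre * n_post) < p), n_pre, n_post)
  if (recurrent) {
    if (n_pre != n_post) stop_param("recurrent masks must be square")
    diag(m) <- 0
  }
  m
}

#' Sample a binary connectivity mask
#'
#' Each admissible directed edge (i -> j) exists independently with
#' probability `p`. For recurrent masks the diagonal (self-connections) is
#' excluded, so the expected density `E / (N (N - 1))` equals `p`.
#'
#' @param n_pre,n_post numbers of pre- and post-synaptic nodes. Recurrent
#'   masks require `n_pre == n_post`.
#' @param p connection probability in \[0, 1\].
#' @param recurrent exclude self-connections (requires a square mask).
#' @param seed integer seed; identical arguments give bit-identical masks.
#' @return a 0/1 numeric matrix; entry (i, j) = 1 means a trainable weight
#'   from node i to node j exists.
#' @export
#' @examples
#' m <- sample_mask(500, 500, 0.1, seed = 1)
#' network_density(m)  # close to 0.1
sample_mask <- function(n_pre, n_post, p, recurrent = TRUE, seed = 1L) {
  if (!is_count(n_pre) || !is_count(n_post)) {
    stop_param("`n_pre` and `n_post` must be positive integers")
  }
  if (!is_prob(p)) stop_param("`p` must be in [0, 1]")
  with_seed(seed, draw_mask(n_pre, n_post, p, recurrent))
}

#' Network density of a recurrent mask
#'
#' `D = E / (N (N - 1))`: the fraction of possible directed edges (excluding
#' self-connections) that are present.
#'
#' @param mask a square 0/1 matrix as returned by [sample_mask()].
#' @return the density, a number in \[0, 1\].
#' @export
network_density <- function(mask) {
  if (!is.matrix(mask) || nrow(mask) != ncol(mask)) {
    stop_param("`mask` must be a square matrix (recurrent hidden layer)")
  }
  n <- nrow(mask)
  sum(mask) / (n * (n - 1))
}

# Unseeded E/I draw.
draw_ei <- function(n, inhibitory_fraction) {
  n_inh <- round(inhibitory_fraction * n)
  signs <- rep(1, n)
  if (n_inh > 0) signs[sample.int(n, n_inh)] <- -1
  signs
}

#' Assign fixed excitatory/inhibitory node identities
#'
#' Exactly `round(inhibitory_fraction * n)` nodes are made inhibitory (-1),
#' at uniformly random positions; the rest are excitatory (+1). The count is
#' exact (not per-node Bernoulli) so the stated inhibitory fraction is
#' honoured deterministically.
#'
#' @param n number of hidden nodes.
#' @param inhibitory_fraction fraction in \[0, 1\] of inhibitory nodes.
#' @param seed integer seed.
#' @return a sign vector of length `n` with entries +1 / -1.
#' @export
#' @examples
#' sum(assign_ei(1000, 0.115, seed = 1) == -1)  # exactly 115
assign_ei <- function(n, inhibitory_fraction, seed = 1L) {
  if (!is_count(n)) stop_param("`n` must be a positive integer")
  if (!is_prob(inhibitory_fraction)) {
    stop_param("`inhibitory_fraction` must be in [0, 1]")
  }
  with_seed(seed, draw_ei(n, inhibitory_fraction))
}

# Unseeded weight draw. Returns the network_params list.
draw_weights <- function(spec, mask, signs, input_dim, n_classes) {
  b <- spec$weight_init_bound
  io_draw <- function(n_in, n_out) {
    if (spec$io_init == "kaiming") {
      lim <- sqrt(1 / n_in)
      matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
    } else {
      matrix(runif(n_in * n_out, -b, b), n_in, n_out)
    }
  }
  if (spec$architecture == "feedforward_2layer") {
    n1 <- nrow(mask)
    n2 <- ncol(mask)
    params <- list(
      w_in = io_draw(input_dim, n1),
      w_hh = matrix(runif(n1 * n2, -b, b), n1, n2) * mask,
      w_out = io_draw(n2, n_classes)
    )
  } else {
    n <- spec$n_hidden
    if (spec$dale) {
      # Magnitude uniform(0, b) times the node's fixed sign; the Dale
      # constraint covers every outgoing weight of a hidden node, i.e. both
      # the hidden-hidden rows and the readout rows. Inhibitory magnitudes
      # are optionally scaled (ten-fold in the strengthened-inhibition
      # manipulation).
      row_scale <- signs * ifelse(signs < 0, spec$inhibitory_scale, 1)
      w_hh <- matrix(runif(n * n, 0, b), n, n) * row_scale * mask
      w_out <- matrix(runif(n * n_classes, 0, b), n, n_classes) * row_scale
      params <- list(
        w_in = io_draw(input_dim, n),
        w_hh = w_hh,
        w_out = w_out
      )
    } else {
      params <- list(
        w_in = io_draw(input_dim, n),
        w_hh = matrix(runif(n * n, -b, b), n, n) * mask,
        w_out = io_draw(n, n_classes)
      )
    }
  }
  if (spec$use_bias) {
    params$b_h <- rep(0, ncol(params$w_in))
    params$b_out <- rep(0, n_classes)
  }
  params$mask <- mask
  params$signs <- signs
  params$activation <- spec$activation
  params$architecture <- spec$architecture
  params$spec <- spec
  class(params) <- "network_params"
  params
}

#' Initialize network weights under mask and Dale constraints
#'
#' Non-Dale networks draw every unmasked hidden-hidden weight uniformly on
#' (-b, b) with b = `weight_init_bound`; Dale networks draw a magnitude
#' uniformly on (0, b) and multiply by the node's fixed sign, with
#' inhibitory rows additionally scaled by `inhibitory_scale`. Masked
#' positions are exactly zero. Input and readout weights use the scheme
#' selected by the spec's `io_init` (same uniform bound by default); under
#' Dale the readout rows inherit the hidden node's sign, while input weights
#' are unconstrained (input nodes carry no E/I identity).
#'
#' @param spec a [connectivity_spec()].
#' @param mask 0/1 connectivity matrix consistent with `spec` (square N x N
#'   for recurrent, N1 x N2 for the feedforward control).
#' @param signs +1/-1 sign vector from [assign_ei()]; required iff
#'   `spec$dale` is `TRUE`.
#' @param input_dim input dimension d (row width of the sequences, or the
#'   flattened length for feedforward networks).
#' @param n_classes number of output classes.
#' @param seed integer seed.
#' @return a `network_params` object: list with `w_in` (input_dim x N),
#'   `w_hh` (N x N, zero wherever the mask is zero), `w_out` (N x
#'   n_classes), optional biases, plus the mask, signs and spec used.
#' @export
init_weights <- function(spec, mask, signs = NULL, input_dim, n_classes,
                         seed = spec$seed) {
  stopifnot(inherits(spec, "connectivity_spec"))
  if (spec$dale && is.null(signs)) {
    stop_param("Dale networks require a `signs` vector (see assign_ei())")
  }
  if (spec$architecture == "recurrent" &&
      !(nrow(mask) == spec$n_hidden && ncol(mask) == spec$n_hidden)) {
    stop_param("mask shape does not match `spec$n_hidden`")
  }
  if (!is.null(signs) && length(signs) != nrow(mask)) {
    stop_param("`signs` length must equal the number of hidden nodes")
  }
  with_seed(seed, draw_weights(spec, mask, signs, input_dim, n_classes))
}

#' Build a complete network from a connectivity spec
#'
#' Convenience wrapper drawing the mask, the E/I sign vector (when Dale) and
#' the initial weights in one seeded sweep from `spec$seed`.
#'
#' @inheritParams init_weights
#' @return a `network_params` object (see [init_weights()]).
#' @export
#' @examples
#' spec <- connectivity_spec(64, 0.1, dale = TRUE, seed = 3)
#' net <- build_network(spec, input_dim = 28, n_classes = 10)
build_network <- function(spec, input_dim, n_classes) {
  stopifnot(inherits(spec, "connectivity_spec"))
  with_seed(spec$seed, {
    if (spec$architecture == "feedforward_2layer") {
      n1 <- spec$n_hidden %/% 2L
      n2 <- spec$n_hidden - n1
      mask <- draw_mask(n1, n2, spec$connection_probability, recurrent = FALSE)
    } else {
      mask <- draw_mask(spec$n_hidden, spec$n_hidden,
                        spec$connection_probability, recurrent = TRUE)
    }
    signs <- if (spec$dale) draw_ei(spec$n_hidden, spec$inhibitory_fraction)
    draw_weights(spec, mask, signs, input_dim, n_classes)
  })
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> %s %s: w_in %dx%d, w_hh %dx%d (%d nonzero), w_out %dx%d%s\n",
    x$architecture, x$activation,
    nrow(x$w_in), ncol(x$w_in), nrow(x$w_hh), ncol(x$w_hh),
    sum(x$w_hh != 0), nrow(x$w_out), ncol(x$w_out),
    if (!is.null(x$signs)) {
      sprintf(", Dale (%d inhibitory)", sum(x$signs < 0))
    } else ""
  ))
  invisible(x)
}

#' Match network sizes to a fixed hidden-layer edge budget
#'
#' For each candidate connection probability, finds the hidden-layer size n
#' whose expected edge count n (n - 1) p is closest to a target, so that
#' sparser networks can be compared with denser ones holding the number of
#' trainable hidden-layer weights constant. Ties in the absolute error break
#' toward the larger n (the sparser, larger network).
#'
#' @param target_edge_count target number of hidden-layer edges (>= 1).
#' @param candidate_p probabilities to match (non-empty, each in \[0, 1\]).
#' @return a data.frame with columns `p`, `n` and `expected_edges`.
#' @export
#' @examples
#' matched_parameter_grid(90, c(1, 0.1))
matched_parameter_grid <- function(target_edge_count, candidate_p) {
  if (!is_count(target_edge_count, min = 1L)) {
    stop_param("`target_edge_count` must be a positive integer")
  }
  if (length(candidate_p) == 0) stop_param("`candidate_p` must be non-empty")
  if (!all(vapply(candidate_p, is_prob, logical(1))) || any(candidate_p <= 0)) {
    stop_param("every candidate p must be in (0, 1]")
  }
  best_n <- vapply(candidate_p, function(p) {
    # n (n - 1) p is monotone in n; search a window around the root.
    n_star <- (1 + sqrt(1 + 4 * target_edge_count / p)) / 2
    candidates <- max(2L, floor(n_star) - 2L):(ceiling(n_star) + 2L)
    err <- abs(candidates * (candidates - 1) * p - target_edge_count)
    # which.max on the reversed order implements the larger-n tie-break
    candidates[length(err) + 1L - which.min(rev(err))]
  }, numeric(1))
  data.frame(
    p = candidate_p,
    n = as.integer(best_n),
    expected_edges = best_n * (best_n - 1) * candidate_p
  )
}
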