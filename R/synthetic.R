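#' Specification of a synthetic row-scanned sequence task
#'
#' Defines a sequence-classification task with the statistical structure of
#' row-scanned images: non-negative inputs bounded in \[0, 1\], a fixed
#' class-dependent spatiotemporal template per class (mostly dark, sparse
#' bright structure), per-sample temporal jitter and additive Gaussian
#' pixel noise.
#'
#' @param n_classes number of classes (default 10).
#' @param seq_len sequence length T (rows per image; default 28).
#' @param input_dim input dimension d (pixels per row; default 28).
#' @param n_train,n_test training and test set sizes (defaults 2000/500;
#'   classes are balanced, so these should be multiples of `n_classes`).
#' @param template_sparsity fraction of nonzero entries in each class
#'   template (default 0.3, mimicking mostly-dark digit images).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 0.1), applied before clipping to \[0, 1\].
#' @param jitter maximum temporal shift (rows) applied uniformly at random
#'   per sample (default 2).
#' @param seed integer seed; the full task is reproducible from the spec.
#' @return an object of class `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(n_classes = 10L,
                                seq_len = 28L,
                                input_dim = 28L,
                                n_train = 2000L,
                                n_test = 500L,
                                template_sparsity = 0.3,
                                noise_sd = 0.1,
                                jitter = 2L,
                                seed = 1L) {
  if (!is_count(n_classes, min = 2L)) stop_param("`n_classes` must be >= 2")
  if (!is_count(seq_len) || !is_count(input_dim)) {
    stop_param("`seq_len` and `input_dim` must be positive integers")
  }
  if (!is_count(n_train) || !is_count(n_test)) {
    stop_param("`n_train` and `n_test` must be positive integers")
  }
  if (!is_prob(template_sparsity)) {
    stop_param("`template_sparsity` must be in [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_param("`noise_sd` must be >= 0")
  if (!is.numeric(jitter) || jitter < 0 || jitter != round(jitter)) {
    stop_param("`jitter` must be a non-negative integer")
  }
  structure(
    list(
      n_classes = as.integer(n_classes),
      seq_len = as.integer(seq_len),
      input_dim = as.integer(input_dim),
      n_train = as.integer(n_train),
      n_test = as.integer(n_test),
      template_sparsity = template_sparsity,
      noise_sd = noise_sd,
      jitter = as.integer(jitter),
      seed = as.integer(seed)
    ),
    class = "synthetic_task_spec"
  )
}

# Shift a T x d template along time by `s` rows (positive = later), zero
# padding the vacated rows.
shift_template <- function(template, s) {
  if (s == 0L) return(template)
  out <- matrix(0, nrow(template), ncol(template))
  T_len <- nrow(template)
  if (s > 0L) {
    out[(s + 1L):T_len, ] <- template[1L:(T_len - s), ]
  } else {
    out[1L:(T_len + s), ] <- template[(1L - s):T_len, ]
  }
  out
}

# Balanced label vector; when n is not a multiple of n_classes the lowest
# class indices receive the remainder.
balanced_labels <- function(n, n_classes) {
  rep(0:(n_classes - 1L), length.out = n)
}

draw_split <- function(templates, labels, spec, split) {
  n <- length(labels)
  arr <- array(0, dim = c(n, spec$seq_len, spec$input_dim))
  for (s in seq_len(n)) {
    shift <- if (spec$jitter > 0L) {
      sample(seq(-spec$jitter, spec$jitter), 1L)
    } else 0L
    x <- shift_template(templates[[labels[s] + 1L]], shift)
    if (spec$noise_sd > 0) {
      x <- x + rnorm(length(x), sd = spec$noise_sd)
    }
    arr[s, , ] <- pmin(pmax(x, 0), 1)
  }
  sequence_dataset(arr, labels, n_classes = spec$n_classes, split = split)
}

#' Generate a synthetic sequence-classification task
#'
#' Per class, a fixed non-negative T x d template is drawn once (a
#' `template_sparsity` fraction of entries uniform on \[0.5, 1\], the rest
#' zero). Each sample is the class template shifted in time by a uniform
#' jitter, plus Gaussian noise, clipped to \[0, 1\]. Train and test samples
#' are disjoint draws with exactly balanced labels.
#'
#' @param spec a [synthetic_task_spec()].
#' @return list with `train` and `test` [sequence_dataset()] splits and
#'   `templates` (the class templates, for inspection and oracle
#'   classifiers).
#' @export
#' @examples
#' task <- make_task(synthetic_task_spec(n_train = 100, n_test = 50))
#' task$train
make_task <- function(spec) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  with_seed(spec$seed, {
    templates <- lapply(seq_len(spec$n_classes), function(cl) {
      nz <- runif(spec$seq_len * spec$input_dim) < spec$template_sparsity
      vals <- runif(spec$seq_len * spec$input_dim, 0.5, 1)
      matrix(nz * vals, spec$seq_len, spec$input_dim)
    })
    train_labels <- balanced_labels(spec$n_train, spec$n_classes)
    test_labels <- balanced_labels(spec$n_test, spec$n_classes)
    train <- draw_split(templates, sample(train_labels), spec, "train")
    test <- draw_split(templates, sample(test_labels), spec, "test")
    list(train = train, test = test, templates = templates)
  })
}

#' Unstructured probe inputs
#'
#' I.i.d. uniform \[0, 1\] sequences with dummy labels, used to probe
#' untrained networks (initialization correlations, activation-magnitude
#' comparisons) with inputs that carry no class structure.
#'
#' @param n number of probe sequences.
#' @param seq_len sequence length T.
#' @param input_dim input dimension d.
#' @param seed integer seed.
#' @return a [sequence_dataset()] with all labels 0.
#' @export
make_probe_inputs <- function(n, seq_len = 28L, input_dim = 28L, seed = 1L) {
  if (!is_count(n)) stop_param("`n` must be >= 1")
  arr <- with_seed(seed, {
    array(runif(n * seq_len * input_dim), dim = c(n, seq_len, input_dim))
  })
  sequence_dataset(arr, rep(0L, n), n_classes = 2L, split = "test")
}
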