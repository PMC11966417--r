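# Experiment orchestration: size x sparsity grids and the Dale
# delay-vs-size protocol, at configurable (desk) scale.

run_single <- function(spec, task, config, seed, delay_margin = 0.02) {
  spec$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  d <- dim(task$train$sequences)
  net <- build_network(spec, input_dim = d[3], n_classes = task$train$n_classes)
  fit <- train_network(net, task$train, task$test, config)
  delay <- training_delay(fit$trace, task$train$n_classes,
                          margin = delay_margin)
  list(
    row = data.frame(
      n_hidden = spec$n_hidden,
      p = spec$connection_probability,
      architecture = spec$architecture,
      activation = spec$activation,
      dale = spec$dale,
      inhibitory_fraction = if (spec$dale) spec$inhibitory_fraction else NA_real_,
      seed = seed,
      single_epoch_accuracy = fit$trace$test_accuracy[1L],
      best_accuracy = max(fit$trace$test_accuracy),
      delay_epochs = delay$delay_epochs,
      epochs_run = nrow(fit$trace),
      final_train_loss = fit$trace$train_loss[nrow(fit$trace)]
    ),
    fit = fit
  )
}

#' Run a grid of network configurations over repeated seeds
#'
#' Trains every connectivity spec in the grid with `n_seeds` different
#' random initializations (seeds `0:(n_seeds - 1)` applied to mask, weight
#' and shuffling draws) and collects per-run metrics: single-epoch test
#' accuracy (time-limited learning), best accuracy over training, and the
#' training delay. A failed run is recorded as a row of `NA`s and the grid
#' continues.
#'
#' @param specs list of [connectivity_spec()] objects (one per grid cell).
#' @param task list with `train` and `test` [sequence_dataset()] splits
#'   (e.g. from [make_task()]).
#' @param config a [training_config()] shared by all runs.
#' @param n_seeds repetitions per spec (default 10).
#' @param delay_margin margin over chance for the delay metric.
#' @return data.frame with one row per (spec, seed).
#' @seealso [summarize_grid()] for mean +/- sd aggregation per spec.
#' @export
run_grid <- function(specs, task, config, n_seeds = 10L, delay_margin = 0.02) {
  if (inherits(specs, "connectivity_spec")) specs <- list(specs)
  rows <- lapply(specs, function(spec) {
    lapply(0:(n_seeds - 1L), function(seed) {
      tryCatch(
        run_single(spec, task, config, seed, delay_margin)$row,
        error = function(e) {
          warning("run failed (N=", spec$n_hidden, ", p=",
                  spec$connection_probability, ", seed=", seed, "): ",
                  conditionMessage(e), call. = FALSE)
          data.frame(
            n_hidden = spec$n_hidden, p = spec$connection_probability,
            architecture = spec$architecture, activation = spec$activation,
            dale = spec$dale,
            inhibitory_fraction = if (spec$dale) spec$inhibitory_fraction else NA_real_,
            seed = seed, single_epoch_accuracy = NA_real_,
            best_accuracy = NA_real_, delay_epochs = NA_real_,
            epochs_run = NA_integer_, final_train_loss = NA_real_
          )
        }
      )
    })
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}

#' Aggregate grid results as mean and standard deviation per spec
#'
#' @param results data.frame from [run_grid()].
#' @param metrics columns to aggregate.
#' @return data.frame with one row per unique (n_hidden, p, architecture,
#'   activation, dale) cell and `<metric>_mean` / `<metric>_sd` columns.
#' @export
summarize_grid <- function(results,
                           metrics = c("single_epoch_accuracy",
                                       "best_accuracy", "delay_epochs")) {
  keys <- c("n_hidden", "p", "architecture", "activation", "dale")
  agg <- aggregate(results[metrics], by = results[keys],
                   FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  out <- agg[keys]
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- agg[[m]][, "mean"]
    out[[paste0(m, "_sd")]] <- agg[[m]][, "sd"]
  }
  out
}

#' Training delay as a function of network size and density
#'
#' The Dale-network protocol: for every (size, p) combination, build
#' Dale-constrained recurrent networks, train them with `n_seeds` seeds and
#' measure the training delay (epochs at chance before learning starts).
#' Dense networks with a cortex-like inhibitory fraction develop a delay
#' that grows with size; sparse ones do not.
#'
#' @param sizes hidden-layer sizes to test.
#' @param p_values connection probabilities to test.
#' @param task list with `train`/`test` splits.
#' @param config a [training_config()]; training can stop early once
#'   accuracy exceeds chance + margin (the delay is then determined) by
#'   setting `stop_at_accuracy`.
#' @param inhibitory_fraction Dale inhibitory fraction (default cortex-like
#'   0.115; 0.5 gives the balanced control).
#' @param inhibitory_scale initial inhibitory magnitude multiplier.
#' @param n_seeds seeds per combination (default 3).
#' @param delay_margin margin over chance defining the crossing.
#' @return list with `runs` (per-run data.frame) and `summary` (mean/sd
#'   delay per size x p; `Inf` delays mean the trace never crossed chance).
#' @export
delay_vs_size <- function(sizes, p_values, task, config,
                          inhibitory_fraction = 0.115,
                          inhibitory_scale = 1,
                          n_seeds = 3L, delay_margin = 0.02) {
  specs <- list()
  for (n in sizes) {
    for (p in p_values) {
      specs[[length(specs) + 1L]] <- connectivity_spec(
        n_hidden = n, connection_probability = p,
        dale = TRUE, inhibitory_fraction = inhibitory_fraction,
        inhibitory_scale = inhibitory_scale
      )
    }
  }
  runs <- run_grid(specs, task, config, n_seeds = n_seeds,
                   delay_margin = delay_margin)
  summary <- summarize_grid(runs, metrics = "delay_epochs")
  list(runs = runs, summary = summary)
}
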