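# Persistence: hierarchical RDS checkpoints keyed by run id and seed, and
# per-epoch run logs as line-delimited JSON / CSV.

#' Save a network checkpoint
#'
#' Stores spec, mask, signs and weight tensors in one hierarchical RDS file
#' keyed by run id and seed, sufficient to resume or re-analyse a run.
#'
#' @param path file path (conventionally `.rds`).
#' @param params a `network_params` object.
#' @param run_id free-form run identifier.
#' @param trace optional training trace to store alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, params, run_id = "run", trace = NULL) {
  stopifnot(inherits(params, "network_params"))
  obj <- list(
    run_id = run_id,
    seed = params$spec$seed,
    spec = params$spec,
    mask = params$mask,
    signs = params$signs,
    weights = params[intersect(c("w_in", "w_hh", "w_out", "b_h", "b_out"),
                               names(params))],
    trace = trace
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @return list with `params` (a rebuilt `network_params` object), `run_id`,
#'   `seed` and `trace`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  params <- obj$weights
  params$mask <- obj$mask
  params$signs <- obj$signs
  params$activation <- obj$spec$activation
  params$architecture <- obj$spec$architecture
  params$spec <- obj$spec
  class(params) <- "network_params"
  list(params = params, run_id = obj$run_id, seed = obj$seed,
       trace = obj$trace)
}

#' Write a training trace as line-delimited JSON
#'
#' One JSON record per epoch, suitable for streaming log collection.
#'
#' @param trace training trace data.frame from [train_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trace))) {
    writeLines(jsonlite::toJSON(as.list(trace[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Write a training trace as CSV
#'
#' @inheritParams write_trace_jsonl
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
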