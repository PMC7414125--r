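#' Export a simulation trace
#'
#' Writes the state trajectory as CSV (columns `time_ms`, unit activities,
#' `I`, `dI`) and, when `jsonlite` is available, a JSON sidecar
#' (`<path>.json`) holding the run metadata (parameters, seed).
#'
#' @param trace Trace data frame from a simulation run.
#' @param path CSV file path.
#' @param params A [circuit_params()] (metadata).
#' @param seed Seed used for the run (metadata).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, params = NULL, seed = NULL) {
  utils::write.csv(trace, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(params = if (!is.null(params)) unclass(params), seed = seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}

#' Generate a synthetic subject summary for fitting
#'
#' Simulates the circuit model at known parameters and writes the behavioral
#' summary that the fitting routines consume, recording the generating
#' ("true") parameters for recovery tests. The output is clearly synthetic:
#' it stands in for a human summary table, produced by the model itself.
#'
#' @param kind `"reproduction"` (10 rows: task, t_s_ms, mean_tp_ms,
#'   sd_tp_ms) or `"sync_cont"` (rows k, bias_ms).
#' @param true_params Named list. For `"reproduction"`: `K`, `I0`,
#'   `sigma_n`. For `"sync_cont"`: `K`, `I0`, `alpha` (with `sigma_n`
#'   optional, default 0.01).
#' @param seed Master seed.
#' @param n_trials Trials per condition (reproduction) or per ISI
#'   (sync/cont).
#' @param path Optional file path; when given the summary is written as CSV.
#' @param params A [circuit_params()].
#' @return The summary data frame, with attribute `true_params`.
#' @export
generate_fixture_subject <- function(kind = c("reproduction", "sync_cont"),
                                     true_params, seed = 1, n_trials = 100,
                                     path = NULL, params = circuit_params()) {
  kind <- match.arg(kind)
  if (kind == "reproduction") {
    out <- reproduction_summary(true_params$K, true_params$I0,
                                true_params$sigma_n, n_trials, seed,
                                params = params)
  } else {
    res <- run_sync_cont(n_trials_per_isi = n_trials, K = true_params$K,
                         I0 = true_params$I0, alpha = true_params$alpha,
                         sigma_n = true_params$sigma_n %||% 0.01,
                         seed = seed, params = params)
    out <- data.frame(k = seq_along(res$bias_k), bias_ms = res$bias_k)
  }
  attr(out, "true_params") <- true_params
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a subject summary CSV
#'
#' @param path CSV path with either reproduction columns (`task`, `t_s_ms`,
#'   `mean_tp_ms`, `sd_tp_ms`) or a bias curve (`k`, `bias_ms`).
#' @return Data frame.
#' @export
read_subject_summary <- function(path) {
  df <- utils::read.csv(path)
  ok_rep <- all(c("task", "t_s_ms", "mean_tp_ms", "sd_tp_ms") %in% names(df))
  ok_sc <- all(c("k", "bias_ms") %in% names(df))
  if (!ok_rep && !ok_sc) {
    stop("unrecognized subject summary format: ", path)
  }
  df
}
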