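#' Simulate periodic production with the motor planning module
#'
#' The motor planning module (MPM) is the BCM plus a self-reset: every
#' threshold crossing of `y_p` registers a production and triggers the reset
#' pulse `I_p` for one pulse duration beginning the step after the crossing,
#' after which the ramp restarts. With a fixed input and no noise the
#' process is strictly periodic after the first cycle; the period grows with
#' the input level.
#'
#' @param params A [circuit_params()].
#' @param I Tonic input level.
#' @param duration Simulation length (ms).
#' @param sigma_n Noise intensity.
#' @param seed Optional RNG seed.
#' @param trace Record the full state trajectory.
#' @return A `production_record`: list with `production_times` (ms), `ipis`
#'   (successive differences, ms), `I`, `seed`, and a `no_productions` flag.
#' @examples
#' rec <- simulate_periodic_production(circuit_params(), I = 0.76,
#'                                     duration = 10000)
#' rec$ipis
#' @export
simulate_periodic_production <- function(params, I, duration,
                                         sigma_n = params$sigma_n,
                                         seed = NULL, trace = FALSE) {
  stopifnot(duration >= params$dt)
  n_steps <- floor(duration / params$dt)
  res <- run_engine(params, I0 = I, n_steps = n_steps, sigma_n = sigma_n,
                    sam_on = FALSE, mpm_on = TRUE, mpm_reset = TRUE,
                    trace = trace, seed = seed)
  production_record(res$production_times, I = I, seed = seed,
                    trace = if (trace) res$trace else NULL)
}

#' Construct a production record
#'
#' @param production_times Strictly increasing production times (ms).
#' @param I Input level (metadata).
#' @param seed RNG seed (metadata).
#' @param trace Optional trace data frame.
#' @return An object of class `production_record`.
#' @export
production_record <- function(production_times, I = NA_real_, seed = NULL,
                              trace = NULL) {
  if (is.unsorted(production_times, strictly = TRUE)) {
    stop("production times must be strictly increasing")
  }
  rec <- list(production_times = production_times,
              ipis = diff(production_times),
              I = I, seed = seed,
              no_productions = length(production_times) == 0)
  if (rec$no_productions) {
    warning("no productions within the simulated duration")
  }
  if (!is.null(trace)) rec$trace <- trace
  class(rec) <- "production_record"
  rec
}

#' @export
print.production_record <- function(x, ...) {
  cat(sprintf("Production record: %d productions", length(x$production_times)))
  if (length(x$ipis)) {
    cat(sprintf(", mean IPI %.0f ms (sd %.0f)", mean(x$ipis),
                if (length(x$ipis) > 1) sd(x$ipis) else 0))
  }
  cat("\n")
  invisible(x)
}
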