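#' Simulate the full coupled circuit
#'
#' The SAM and MPM share the input `I`: stimuli reset the SAM and drive the
#' gated input update; the MPM free-runs, resetting itself after each
#' production. The phase-correction pathway adds `dI = alpha * (y_p - y_s)`
#' to the MPM's tonic drive (through the same input weights), speeding the
#' MPM up when it lags the SAM (`y_s > y_p`) and slowing it when it leads.
#' `dI` is recomputed from the current state at every step; it is not
#' integrated. Productions never reset the SAM.
#'
#' @param params A [circuit_params()].
#' @param config A [coupled_config()].
#' @param stimuli A [stimulus_train()].
#' @param duration Total simulated time (ms); defaults to the last onset plus
#'   1.5 times the last ISI.
#' @param sigma_n Noise intensity.
#' @param seed Optional RNG seed.
#' @param trace Record the state trajectory.
#' @return List with `production` (a [production_record()]), `I_final`, and
#'   optionally `trace`.
#' @export
simulate_coupled <- function(params, config, stimuli, duration = NULL,
                             sigma_n = params$sigma_n, seed = NULL,
                             trace = FALSE) {
  stopifnot(inherits(config, "coupled_config"),
            inherits(stimuli, "stimulus_train"))
  if (is.null(duration)) {
    last_isi <- if (length(stimuli$isis)) stimuli$isis[length(stimuli$isis)] else 1000
    duration <- max(stimuli$onsets) + 1.5 * last_isi
  }
  n_steps <- floor(duration / params$dt)
  sam <- config$sam
  res <- run_engine(params, I0 = sam$I0, K = sam$K, alpha = config$alpha,
                    stim_steps = stim_step_indices(stimuli, params),
                    first_pulse_end = first_pulse_last_step(stimuli, params,
                                                            sam$first_stim_frozen),
                    n_steps = n_steps, sigma_n = sigma_n,
                    sam_on = TRUE, mpm_on = TRUE, mpm_reset = TRUE,
                    trace = trace, seed = seed)
  out <- list(production = suppressWarnings(
                production_record(res$production_times, seed = seed)),
              I_final = res$I_final, diverged = res$diverged)
  if (trace) out$trace <- res$trace
  out
}
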