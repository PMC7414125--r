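# Map a stimulus train onto engine step indices: a stimulus with onset o is
# "on" for pulse_dur/dt steps starting at step o/dt + 1.
stim_step_indices <- function(train, params) {
  k <- max(1L, as.integer(round(train$pulse_dur / params$dt)))
  idx0 <- round(train$onsets / params$dt)
  as.integer(outer(idx0, seq_len(k), `+`))
}

# Last step (1-based) of the first stimulus pulse, used to freeze the input
# update before any interval has been observed.
first_pulse_last_step <- function(train, params, frozen = TRUE) {
  if (!frozen) return(0L)
  k <- max(1L, as.integer(round(train$pulse_dur / params$dt)))
  as.integer(round(train$onsets[1] / params$dt) + k)
}

#' Simulate the sensory anticipation module
#'
#' The SAM is the BCM reset by stimuli rather than by its own output: each
#' stimulus delivers the pulse `I_s` to `u_s` and `v_s`, and while the
#' stimulus is on the shared input is advanced at a rate proportional to the
#' anticipation error, `tau * dI/dt = s * K * (y_s - y0)`. The update is
#' frozen during the first stimulus (no interval measured yet). Between
#' stimuli `I` is constant. The module registers no motor output; the times
#' at which `y_s` crosses `y0` from below are its anticipated event times.
#'
#' @param params A [circuit_params()].
#' @param config A [sam_config()].
#' @param stimuli A [stimulus_train()].
#' @param duration Total simulated time (ms); defaults to the last onset plus
#'   three times the last ISI (or 3 s for a single stimulus).
#' @param sigma_n Noise intensity.
#' @param seed Optional RNG seed.
#' @param trace Record the state trajectory.
#' @return List with `predicted_times` (upward `y_s` crossings, ms),
#'   `I_final`, and optionally `trace`.
#' @export
simulate_sam <- function(params, config, stimuli, duration = NULL,
                         sigma_n = params$sigma_n, seed = NULL,
                         trace = FALSE) {
  stopifnot(inherits(config, "sam_config"), inherits(stimuli, "stimulus_train"))
  if (is.null(duration)) {
    last_isi <- if (length(stimuli$isis)) stimuli$isis[length(stimuli$isis)] else 1000
    duration <- max(stimuli$onsets) + 3 * last_isi
  }
  n_steps <- floor(duration / params$dt)
  res <- run_engine(params, I0 = config$I0, K = config$K,
                    stim_steps = stim_step_indices(stimuli, params),
                    first_pulse_end = first_pulse_last_step(stimuli, params,
                                                            config$first_stim_frozen),
                    n_steps = n_steps, sigma_n = sigma_n,
                    sam_on = TRUE, mpm_on = FALSE, trace = trace, seed = seed)
  out <- list(predicted_times = res$sam_cross_times, I_final = res$I_final,
              diverged = res$diverged)
  if (trace) out$trace <- res$trace[, c("time_ms", "u_s", "v_s", "y_s", "I")]
  out
}

#' Reproduce a time interval with the SAM
#'
#' Models the 1-2-Go (`n_flashes = 2`) and 1-2-3-Go (`n_flashes = 3`)
#' interval-reproduction tasks. After a run-in, `n_flashes` stimuli are
#' presented separated by the sample interval `t_s`; the produced interval
#' `t_p` is the time from the final flash onset to the next upward crossing
#' of `y_s` through `y0`. If no crossing occurs within `guard * t_s` after
#' the final flash the trial is recorded as missing (`NA`).
#'
#' @param params A [circuit_params()].
#' @param config A [sam_config()].
#' @param t_s Sample interval (ms).
#' @param n_flashes 2 or 3.
#' @param sigma_n Noise intensity.
#' @param seed Optional RNG seed.
#' @param guard Guard window in units of `t_s`.
#' @return Produced interval `t_p` in ms, or `NA` if missing.
#' @export
reproduce_interval <- function(params, config, t_s, n_flashes = 2,
                               sigma_n = params$sigma_n, seed = NULL,
                               guard = 3) {
  stopifnot(t_s > 0, n_flashes %in% c(2, 3))
  train <- make_isochronous(t_s, n_flashes, start = params$run_in)
  last <- max(train$onsets)
  sim <- simulate_sam(params, config, train, duration = last + guard * t_s,
                      sigma_n = sigma_n, seed = seed, trace = TRUE)
  cross <- anticipation_crossing(sim$trace, after_ms = last, y0 = params$y0)
  if (!is.finite(cross)) return(NA_real_)
  cross - last
}

# First upward y_s crossing after `after_ms` that follows the stimulus reset
# taking effect, i.e. after y_s has been below threshold at some step
# strictly later than `after_ms`. Because y_s follows u_s - v_s with a lag,
# it can still be rising through y0 during the flash itself; such residual
# crossings do not reflect a new anticipated interval and are skipped.
anticipation_crossing <- function(trace, after_ms, y0) {
  t <- trace$time_ms
  ys <- trace$y_s
  below_seen <- FALSE
  for (j in which(t > after_ms)) {
    if (below_seen && ys[j] >= y0 && ys[j - 1] < y0) return(t[j])
    if (ys[j] < y0) below_seen <- TRUE
  }
  NA_real_
}
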