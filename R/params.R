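#' Circuit parameters
#'
#' Container for the weights, time constants and amplitudes of the basic
#' circuit module (BCM) and its derivatives. Two units `u` and `v` inhibit one
#' another with weights `w_uv`, `w_vu`, receive a shared tonic input `I`
#' through `w_uI`, `w_vI`, and drive an output unit `y` with weights `w_yu`
#' (excitatory) and `w_yv` (inhibitory). A movement is initiated when `y`
#' crosses the threshold `y0`. All units share the time constant `tau` and are
#' integrated with forward Euler steps of size `dt`.
#'
#' `I_p` and `I_s` are the amplitudes of the motor-reset and stimulus pulses,
#' delivered inside the sigmoid arguments of `u` and `v` (negative to `u`,
#' positive to `v`) for `pulse_dur` milliseconds. At the default amplitude of
#' 50 the sigmoid arguments saturate, so the pulse drives `u` toward 0 and `v`
#' toward 1 for as long as it lasts.
#'
#' @param tau Unit time constant (ms).
#' @param w_uI,w_vI Input weights.
#' @param w_uv,w_vu Mutual-inhibition weights.
#' @param w_yu,w_yv Output weights.
#' @param y0 Output threshold for action initiation / anticipation.
#' @param I_p Motor reset pulse amplitude.
#' @param I_s Stimulus pulse amplitude.
#' @param sigma_n Noise intensity (dimensionless; see [noise_step_sd()] for
#'   the discretization convention).
#' @param dt Euler integration step (ms).
#' @param pulse_dur Duration of reset/stimulus pulses (ms); must be a multiple
#'   of `dt`.
#' @param u_init,v_init,y_init Initial activities.
#' @param run_in Settling time before the first stimulus (ms).
#'
#' @return An object of class `circuit_params` (a named list).
#' @examples
#' p <- circuit_params()
#' p$tau
#' @export
circuit_params <- function(tau = 100, w_uI = 6, w_vI = 6, w_uv = 6, w_vu = 6,
                           w_yu = 1, w_yv = 1, y0 = 0.7, I_p = 50, I_s = 50,
                           sigma_n = 0, dt = 10, pulse_dur = 10,
                           u_init = 0.7, v_init = 0.2, y_init = 0.5,
                           run_in = 750) {
  stopifnot(tau > 0, dt > 0, dt <= tau, sigma_n >= 0,
            y0 > 0, y0 < 1, pulse_dur >= dt)
  is_multiple <- function(x) abs(x / dt - round(x / dt)) < 1e-8
  if (!is_multiple(pulse_dur)) {
    stop("`pulse_dur` must be a multiple of `dt`")
  }
  if (!is_multiple(run_in)) {
    stop("`run_in` must be a multiple of `dt`")
  }
  p <- list(tau = tau, w_uI = w_uI, w_vI = w_vI, w_uv = w_uv, w_vu = w_vu,
            w_yu = w_yu, w_yv = w_yv, y0 = y0, I_p = I_p, I_s = I_s,
            sigma_n = sigma_n, dt = dt, pulse_dur = pulse_dur,
            u_init = u_init, v_init = v_init, y_init = y_init,
            run_in = run_in, reset_steps = as.integer(pulse_dur / dt))
  class(p) <- "circuit_params"
  p
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Circuit parameters\n")
  cat(sprintf("  tau = %g ms, dt = %g ms, pulse = %g ms, run-in = %g ms\n",
              x$tau, x$dt, x$pulse_dur, x$run_in))
  cat(sprintf("  weights: w_uI = w_vI = %g, w_uv = w_vu = %g, w_y = (%g, -%g)\n",
              x$w_uI, x$w_uv, x$w_yu, x$w_yv))
  cat(sprintf("  threshold y0 = %g, pulses I_p = %g, I_s = %g, sigma_n = %g\n",
              x$y0, x$I_p, x$I_s, x$sigma_n))
  invisible(x)
}

#' Sensory anticipation module configuration
#'
#' The sensory anticipation module (SAM) adjusts the shared input `I` at every
#' stimulus at a rate proportional to the anticipation error `y_s - y0`,
#' scaled by the update gain `K`. The update is gated by the stimulus signal
#' and (when `first_stim_frozen`) suppressed during the first stimulus of a
#' run, before any interval has been observed.
#'
#' @param K Update gain (>= 0).
#' @param I0 Initial level of the shared input.
#' @param first_stim_frozen Freeze the update during the first stimulus pulse.
#' @return An object of class `sam_config`.
#' @export
sam_config <- function(K = 2, I0 = 0.771, first_stim_frozen = TRUE) {
  stopifnot(K >= 0, is.finite(I0))
  structure(list(K = K, I0 = I0, first_stim_frozen = isTRUE(first_stim_frozen)),
            class = "sam_config")
}

#' Coupled-circuit configuration
#'
#' Full model: SAM and motor planning module (MPM) share the input `I`, and a
#' phase-correction signal `dI = alpha * (y_p - y_s)` augments the MPM's
#' drive. `alpha = 0` removes the pathway and reduces the model exactly to
#' the uncoupled shared-input circuit.
#'
#' @param sam A [sam_config()].
#' @param alpha Phase-correction gain (>= 0).
#' @return An object of class `coupled_config`.
#' @export
coupled_config <- function(sam = sam_config(), alpha = 0) {
  stopifnot(inherits(sam, "sam_config"), alpha >= 0)
  structure(list(sam = sam, alpha = alpha), class = "coupled_config")
}
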