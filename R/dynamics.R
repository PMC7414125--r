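#' Logistic activation function
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, the activation of every circuit unit.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @examples
#' sigmoid(0)              # 0.5
#' sigmoid(3) + sigmoid(-3) # 1
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Per-step noise standard deviation
#'
#' The stochastic inputs eta_u, eta_v, eta_y are Gaussian with zero mean and
#' standard deviation `sigma_n`, drawn independently at every integration
#' step. `sigma_n` is defined as the per-step SD at the reference step size
#' of 10 ms; no `dt` scaling is applied, so changing `dt` changes the
#' effective noise process. Simulations warn when run with `dt != 10` and
#' `sigma_n > 0`.
#'
#' @param params A [circuit_params()].
#' @param sigma_n Noise intensity; defaults to the value in `params`.
#' @return The per-step SD (equal to `sigma_n`).
#' @export
noise_step_sd <- function(params, sigma_n = params$sigma_n) {
  stopifnot(sigma_n >= 0)
  sigma_n
}

#' Draw per-step unit noise
#'
#' Independent Gaussian draws, one per unit per step, at the per-step SD
#' implied by `sigma_n` (see [noise_step_sd()]). With `sigma_n = 0` an exact
#' zero vector is returned without consuming random numbers.
#'
#' @param sigma_n Noise intensity (>= 0).
#' @param n Number of draws.
#' @param params A [circuit_params()] supplying `dt` and `tau`.
#' @return Numeric vector of length `n`.
#' @export
draw_noise <- function(sigma_n, n, params = circuit_params()) {
  if (sigma_n < 0) stop("`sigma_n` must be >= 0")
  if (sigma_n == 0) return(numeric(n))
  rnorm(n, 0, noise_step_sd(params, sigma_n))
}

#' Advance the basic circuit module by one Euler step
#'
#' Reference (pure R) implementation of a single synchronous forward-Euler
#' step of the three-unit dynamics: all derivatives are evaluated at the
#' current state, then every unit is advanced together. `eta[1:2]` enter
#' inside the sigmoid arguments of `u` and `v`; `eta[3]` adds linearly to the
#' drive of `y`. `extra_u` and `extra_v` are signed additive terms inside the
#' sigmoid arguments, used by the motor and sensory modules to deliver reset
#' and stimulus pulses (zero for the plain BCM).
#'
#' The compiled simulators use the identical update; this function is the
#' single-step primitive for inspection, testing and fine-step reference
#' integration.
#'
#' @param state Named list or vector with elements `u`, `v`, `y`.
#' @param I Tonic input.
#' @param params A [circuit_params()].
#' @param eta Length-3 noise vector (per-step draws).
#' @param extra_u,extra_v Additive drive terms inside the sigmoid arguments.
#' @return Updated state (list with `u`, `v`, `y`).
#' @export
step_bcm <- function(state, I, params, eta = c(0, 0, 0),
                     extra_u = 0, extra_v = 0) {
  r <- params$dt / params$tau
  u <- state$u; v <- state$v; y <- state$y
  if (!all(is.finite(c(u, v, y)))) stop("non-finite state: numerical divergence")
  u_new <- u + r * (-u + sigmoid(params$w_uI * I - params$w_uv * v + eta[1] + extra_u))
  v_new <- v + r * (-v + sigmoid(params$w_vI * I - params$w_vu * u + eta[2] + extra_v))
  y_new <- y + r * (-y + params$w_yu * u - params$w_yv * v + eta[3])
  list(u = u_new, v = v_new, y = y_new)
}

# Internal wrapper around the compiled engine. Returns production times,
# SAM crossing times (ms) and optionally the full trace as a data.frame.
run_engine <- function(params, I0, K = 0, alpha = 0,
                       stim_steps = integer(0), first_pulse_end = 0L,
                       n_steps, sigma_n = 0, sam_on = FALSE, mpm_on = TRUE,
                       mpm_reset = TRUE, trace = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma_n > 0 && params$dt != 10) {
    warning("sigma_n is calibrated as the per-step noise SD at dt = 10 ms; ",
            "with dt = ", params$dt, " the effective noise process differs")
  }
  stim <- integer(n_steps)
  stim[stim_steps[stim_steps >= 1 & stim_steps <= n_steps]] <- 1L
  res <- cpp_run_circuit(unclass(params), I0, K, alpha, stim,
                         as.integer(first_pulse_end), as.integer(n_steps),
                         noise_step_sd(params, sigma_n),
                         sam_on, mpm_on, mpm_reset, trace)
  if (res$diverged) warning("simulation diverged to non-finite state")
  out <- list(production_times = res$prod_steps * params$dt,
              sam_cross_times = res$sam_cross_steps * params$dt,
              I_final = res$I_final,
              diverged = res$diverged)
  if (trace) {
    tr <- as.data.frame(res$trace)
    names(tr) <- c("u_s", "v_s", "y_s", "u_p", "v_p", "y_p", "I", "dI")
    tr <- cbind(time_ms = seq_len(nrow(tr)) * params$dt, tr)
    out$trace <- tr
  }
  out
}

#' Simulate the basic circuit module
#'
#' Integrates the BCM from its initial conditions under a constant tonic
#' input and reports the first time the output crosses the threshold `y0`
#' (the modeled movement-initiation time). The crossing is detected after
#' each full step as `y >= y0` with `y < y0` at the previous step; no
#' sub-step interpolation is performed, so crossing times are reported at
#' `dt` resolution.
#'
#' @param params A [circuit_params()].
#' @param I Tonic input level. Larger inputs slow the ramp and delay (or
#'   prevent) the crossing.
#' @param duration Simulation length (ms).
#' @param sigma_n Noise intensity (default: value in `params`).
#' @param seed Optional RNG seed.
#' @param trace Record the full state trajectory.
#' @return A list with `first_crossing` (ms, or `NA` if no crossing),
#'   and, if requested, `trace` (a data frame with one row per step).
#' @examples
#' sim <- simulate_bcm(circuit_params(), I = 0.75, duration = 2000)
#' sim$first_crossing
#' @export
simulate_bcm <- function(params, I, duration, sigma_n = params$sigma_n,
                         seed = NULL, trace = FALSE) {
  stopifnot(duration >= params$dt)
  n_steps <- floor(duration / params$dt)
  res <- run_engine(params, I0 = I, n_steps = n_steps, sigma_n = sigma_n,
                    sam_on = FALSE, mpm_on = TRUE, mpm_reset = FALSE,
                    trace = trace, seed = seed)
  cross <- res$production_times
  out <- list(first_crossing = if (length(cross)) cross[1] else NA_real_,
              diverged = res$diverged)
  if (trace) {
    tr <- res$trace[, c("time_ms", "u_p", "v_p", "y_p", "I", "dI")]
    names(tr) <- c("time_ms", "u", "v", "y", "I", "dI")
    out$trace <- tr
  }
  out
}
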