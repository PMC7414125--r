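#' Linear error-correction timing model
#'
#' Parameters of the algorithmic baseline: production times are updated by
#' `t[n+1] = t[n] + T[n] - beta_asynch * (t[n] - m[n]) - beta_isi * (T[n] -
#' ISI[n]) + eta`, where `T` is the internal estimate of the interval,
#' updated as `T[n+1] = T[n] - beta_isi * (T[n] - ISI[n])` (exponential
#' tracking of the observed ISI), and `eta` is Gaussian production noise.
#'
#' @param T0 Initial expected interval (ms).
#' @param beta_isi Interval-correction weight.
#' @param beta_asynch Asynchrony-correction weight.
#' @param sigma_n Production-noise SD (ms).
#' @return An object of class `linear_params`.
#' @export
linear_params <- function(T0 = 800, beta_isi = 0.5, beta_asynch = 0,
                          sigma_n = 0) {
  stopifnot(sigma_n >= 0)
  structure(list(T0 = T0, beta_isi = beta_isi, beta_asynch = beta_asynch,
                 sigma_n = sigma_n), class = "linear_params")
}

#' One update of the linear timing model
#'
#' @param t_n Current production time (ms).
#' @param T_n Current interval estimate (ms).
#' @param m_n Time of the metronomic input matched to `t_n` (ms).
#' @param isi_n Observed inter-stimulus interval (ms).
#' @param params A [linear_params()].
#' @param noise Noise draw added to the next production time (ms).
#' @return List with `t_next` and `T_next`.
#' @export
step_linear <- function(t_n, T_n, m_n, isi_n, params, noise = 0) {
  t_next <- t_n + T_n - params$beta_asynch * (t_n - m_n) -
    params$beta_isi * (T_n - isi_n) + noise
  T_next <- T_n - params$beta_isi * (T_n - isi_n)
  list(t_next = t_next, T_next = T_next)
}

#' Interval reproduction with the linear model
#'
#' In the reproduction tasks the model observes `n_flashes - 1` intervals
#' equal to the sample interval, updating its estimate after each, and then
#' produces `t_p = T + eta`. With `beta_isi = 0` the production equals the
#' prior `T0` regardless of the sample; with `beta_isi = 1` it matches the
#' sample (up to noise); intermediate values give a central-tendency bias
#' that shrinks geometrically with the number of observations.
#'
#' @param params A [linear_params()].
#' @param task `"12go"` or `"123go"`.
#' @param t_s_values Sample intervals (ms).
#' @param n_trials Trials per sample interval.
#' @param seed Master seed.
#' @return Data frame with columns `task`, `t_s`, `trial`, `t_p`.
#' @export
simulate_linear_reproduction <- function(params, task = c("12go", "123go"),
                                         t_s_values = seq(600, 1000, 100),
                                         n_trials = 100, seed = 1) {
  task <- match.arg(task)
  n_obs <- if (task == "12go") 1 else 2
  out <- expand.grid(t_s = t_s_values, trial = seq_len(n_trials))
  out$t_p <- mapply(function(ts, tr) {
    set.seed(derive_seed(seed, 800 + n_obs, tr * 1000 + match(ts, t_s_values)))
    Tn <- params$T0
    for (i in seq_len(n_obs)) Tn <- Tn - params$beta_isi * (Tn - ts)
    Tn + rnorm(1, 0, params$sigma_n)
  }, out$t_s, out$trial)
  cbind(task = task, out)
}

#' Synchronization/continuation with the linear model
#'
#' During synchronization the model taps according to the full update rule
#' while observing the metronome; after the final stimulus the interval
#' estimate is frozen at its last value `T_N`, and continuation productions
#' follow `t[n+1] = t[n] + T_N + eta`. Continuation IPIs therefore have a
#' constant mean, so the per-index continuation bias is flat - the key
#' contrast with the circuit model.
#'
#' @param params A [linear_params()].
#' @param isi Trial ISI (ms).
#' @param n_sync Number of synchronization stimuli.
#' @param n_ipis Number of IPIs returned.
#' @param seed RNG seed.
#' @param start Time of the first stimulus (ms).
#' @return Numeric vector of IPIs (ms), length `n_ipis`.
#' @export
simulate_linear_sync_cont <- function(params, isi, n_sync = 3, n_ipis = 20,
                                      seed = 1, start = 750) {
  set.seed(seed)
  m <- start + isi * (seq_len(n_sync) - 1)
  Tn <- params$T0
  # first tap aligned with the first stimulus, before any ISI is observed
  t <- m[1] + rnorm(1, 0, params$sigma_n)
  taps <- t
  for (n in seq_len(n_sync - 1)) {
    st <- step_linear(taps[n], Tn, m[n], isi, params,
                      noise = rnorm(1, 0, params$sigma_n))
    taps <- c(taps, st$t_next)
    Tn <- st$T_next
  }
  # continuation with frozen T
  while (length(taps) < n_ipis + 1) {
    taps <- c(taps, taps[length(taps)] + Tn + rnorm(1, 0, params$sigma_n))
  }
  diff(taps)[seq_len(n_ipis)]
}

#' Synchronization/continuation task for the linear model
#'
#' Mirrors [run_sync_cont()] so that the two models can be compared on the
#' same protocol and with the same bias metric.
#'
#' @param params A [linear_params()].
#' @param n_trials_per_isi Trials per ISI.
#' @param isis ISI grid.
#' @param n_ipis IPIs per trial.
#' @param seed Master seed.
#' @return List with `mean_ipi` (ISI x k), `bias_k`, `isis`.
#' @export
run_linear_sync_cont <- function(params, n_trials_per_isi = 21,
                                 isis = sync_cont_grid(), n_ipis = 20,
                                 seed = 1) {
  arr <- array(NA_real_, c(length(isis), n_trials_per_isi, n_ipis))
  for (ci in seq_along(isis)) {
    for (tr in seq_len(n_trials_per_isi)) {
      arr[ci, tr, ] <- simulate_linear_sync_cont(
        params, isis[ci], n_ipis = n_ipis,
        seed = derive_seed(seed, 900 + ci, tr))
    }
  }
  mean_ipi <- apply(arr, c(1, 3), mean, na.rm = TRUE)
  list(mean_ipi = mean_ipi, bias_k = bias_by_index(mean_ipi, isis),
       isis = isis)
}
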