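#' Deterministic trial seed derivation
#'
#' Counter-based scheme: the seed of trial `trial` in condition `condition`
#' depends only on (`master`, `condition`, `trial`), so adding trials or
#' conditions never changes earlier trials.
#'
#' @param master Master seed (integer).
#' @param condition Condition index (integer >= 0).
#' @param trial Trial index (integer >= 1).
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, condition, trial) {
  # arithmetic in doubles (exact below 2^53), reduced before integer cast
  val <- ((abs(master) %% 1e6) * 2039 + condition * 7919 +
            trial * 104729) %% 2147483646
  as.integer(val) + 1L
}

#' Periodic-production task
#'
#' Simulates the MPM in isolation at each input level for `duration` ms and
#' collects the IPIs, emulating an experiment in which the produced tempo is
#' read out at several levels of the tonic input.
#'
#' @param I_levels Input levels.
#' @param duration Per-level simulation length (ms).
#' @param n_trials Trials per level.
#' @param sigma_n Noise intensity.
#' @param seed Master seed.
#' @param params A [circuit_params()].
#' @param first_n If finite, keep only the first `first_n` IPIs per trial.
#' @return A data frame with columns `I`, `trial`, `k` (IPI index), `ipi`.
#' @export
run_periodic <- function(I_levels = c(0.75, 0.76, 0.77, 0.78),
                         duration = 40000, n_trials = 1, sigma_n = 0.01,
                         seed = 1, params = circuit_params(),
                         first_n = 40) {
  out <- list()
  for (ci in seq_along(I_levels)) {
    for (tr in seq_len(n_trials)) {
      rec <- suppressWarnings(simulate_periodic_production(
        params, I_levels[ci], duration, sigma_n = sigma_n,
        seed = derive_seed(seed, ci, tr)))
      ip <- rec$ipis
      if (is.finite(first_n)) ip <- utils::head(ip, first_n)
      if (length(ip)) {
        out[[length(out) + 1]] <- data.frame(I = I_levels[ci], trial = tr,
                                             k = seq_along(ip), ipi = ip)
      }
    }
  }
  do.call(rbind, out)
}

#' ISI tracking task
#'
#' Runs the coupled circuit on the blocked tracking protocol (one train per
#' trial; see [make_tracking_blocks()]) and associates every IPI with the
#' stimulus interval within which it began, and every stimulus with its
#' nearest production.
#'
#' @param n_trials Number of trials.
#' @param alpha Phase-correction gain (0 disables the pathway).
#' @param K Input-update gain.
#' @param I0 Initial input.
#' @param sigma_n Noise intensity.
#' @param seed Master seed.
#' @param params A [circuit_params()].
#' @return A list of class `tracking_result`: `pairs` (per-IPI rows with the
#'   associated ISI), `phases` (per-stimulus asynchrony/phase rows with
#'   `trial`), and the run configuration.
#' @export
run_tracking <- function(n_trials = 50, alpha = 0, K = 2, I0 = 0.771,
                         sigma_n = 0.01, seed = 1,
                         params = circuit_params()) {
  cfg <- coupled_config(sam_config(K = K, I0 = I0), alpha = alpha)
  pairs <- list(); phases <- list(); seqs <- list()
  for (tr in seq_len(n_trials)) {
    train <- make_tracking_blocks(seed = derive_seed(seed, 1, tr))
    sim <- simulate_coupled(params, cfg, train,
                            duration = max(train$onsets) + 1000,
                            sigma_n = sigma_n, seed = derive_seed(seed, 2, tr))
    prod <- sim$production$production_times
    if (length(prod) < 3) next
    ipis <- diff(prod)
    iv <- findInterval(prod[-length(prod)], train$onsets)
    keep <- iv >= 1 & iv <= length(train$isis)
    pairs[[tr]] <- data.frame(trial = tr, isi = train$isis[iv[keep]],
                              ipi = ipis[keep], block = ceiling(iv[keep] / 20))
    # index-paired sequences: the nth produced interval against the nth
    # stimulus interval
    pseq <- prod[prod >= train$onsets[1]]
    iseq <- diff(pseq)
    k <- min(length(iseq), length(train$isis))
    seqs[[tr]] <- data.frame(trial = tr, n = seq_len(k),
                             isi = train$isis[seq_len(k)],
                             ipi = iseq[seq_len(k)])
    ap <- asynchrony_phase(prod, train)
    ap$trial <- tr
    phases[[tr]] <- ap
  }
  structure(list(pairs = do.call(rbind, pairs),
                 sequences = do.call(rbind, seqs),
                 phases = do.call(rbind, phases),
                 config = list(n_trials = n_trials, alpha = alpha, K = K,
                               I0 = I0, sigma_n = sigma_n, seed = seed)),
            class = "tracking_result")
}

#' Summarize IPI-vs-ISI tracking
#'
#' Regression summaries of a [run_tracking()] result at three levels:
#' pooled per-interval (ISI, IPI) pairs (time-associated), per-trial mean
#' IPI for each ISI, and the within-trial coefficient of determination of
#' the index-paired sequences (the nth produced interval against the nth
#' stimulus interval), averaged across trials. The last is the package's
#' headline tracking statistic: each trial is an independent run of the
#' protocol, and the statistic summarizes how lawfully the produced
#' intervals follow the stimulus intervals within a run.
#'
#' @param result A `tracking_result`.
#' @return List with `r2_pairs`, `r2_trial_means`, `r2_within_trial`
#'   (the mean within-trial sequence r-squared), `fit_trial_means` and the
#'   per-trial condition means `trial_means`.
#' @export
analyze_tracking <- function(result) {
  stopifnot(inherits(result, "tracking_result"))
  p <- result$pairs
  tm <- aggregate(ipi ~ isi + trial, p, mean)
  f1 <- linear_fit_r2(p$isi, p$ipi)
  f2 <- linear_fit_r2(tm$isi, tm$ipi)
  r2w <- vapply(split(result$sequences, result$sequences$trial), function(d) {
    if (var(d$isi) == 0) return(NA_real_)
    linear_fit_r2(d$isi, d$ipi)$r2
  }, numeric(1))
  list(r2_pairs = f1$r2, r2_trial_means = f2$r2,
       r2_within_trial = mean(r2w, na.rm = TRUE),
       fit_trial_means = f2, trial_means = tm)
}

#' ISI perturbation task
#'
#' Simulates the coupled circuit on a perturbation protocol (see
#' [make_perturbation()]) for many trials, aligning trials on the index of
#' the first perturbed stimulus, and returning per-index means of IPI and
#' asynchrony. For phase-shift analyses the pre-perturbation mean asynchrony
#' is subtracted (`asynch_rel`).
#'
#' @param kind `"step"`, `"phase_shift"` or `"jitter"`.
#' @param n_trials Number of trials.
#' @param K Input-update gain.
#' @param alpha Phase-correction gain.
#' @param I0 Initial input; by default chosen per protocol so the initial
#'   tempo matches the pre-perturbation ISI (0.7745 for the 800 ms step
#'   baseline, 0.766 for the 500 ms baselines).
#' @param sigma_n Noise intensity.
#' @param seed Master seed.
#' @param params A [circuit_params()].
#' @return List with `by_index` (stimulus-indexed means: `mean_asynch`,
#'   `asynch_rel`, `mean_ipi`), `pert_index`, and the configuration.
#' @export
run_perturbation <- function(kind = c("step", "phase_shift", "jitter"),
                             n_trials = 200, K = 2, alpha = 0.1, I0 = NULL,
                             sigma_n = 0.005, seed = 1,
                             params = circuit_params()) {
  kind <- match.arg(kind)
  if (is.null(I0)) I0 <- if (kind == "step") 0.7745 else 0.766
  cfg <- coupled_config(sam_config(K = K, I0 = I0), alpha = alpha)
  train <- make_perturbation(kind)
  m <- train$onsets[-length(train$onsets)]
  nm <- length(m)
  asyn <- matrix(NA_real_, n_trials, nm)
  ipi_at <- matrix(NA_real_, n_trials, nm)
  for (tr in seq_len(n_trials)) {
    sim <- simulate_coupled(params, cfg, train,
                            duration = max(train$onsets) + 1500,
                            sigma_n = sigma_n, seed = derive_seed(seed, 3, tr))
    prod <- sim$production$production_times
    if (length(prod) < 3) next
    ap <- asynchrony_phase(prod, train)
    asyn[tr, ] <- ap$asynchrony_ms
    # IPI containing each stimulus interval start
    ipis <- diff(prod)
    iv <- findInterval(prod[-length(prod)], train$onsets)
    for (n in seq_len(nm)) {
      hit <- which(iv == n)
      if (length(hit)) ipi_at[tr, n] <- mean(ipis[hit])
    }
  }
  pert <- train$meta$pert_index
  mean_asynch <- colMeans(asyn, na.rm = TRUE)
  base <- mean(mean_asynch[(pert - 10):(pert - 1)])
  list(by_index = data.frame(stim_index = seq_len(nm),
                             isi = train$isis,
                             mean_asynch = mean_asynch,
                             asynch_rel = mean_asynch - base,
                             mean_ipi = colMeans(ipi_at, na.rm = TRUE)),
       pert_index = pert,
       config = list(kind = kind, n_trials = n_trials, K = K, alpha = alpha,
                     I0 = I0, sigma_n = sigma_n, seed = seed))
}

#' Synchronization/continuation task
#'
#' For each ISI of the task grid, simulates the coupled circuit with three
#' flashes and lets it produce freely afterwards; collects the first
#' `n_ipis` inter-production intervals of each trial (synchronization and
#' continuation phases combined).
#'
#' @param n_trials_per_isi Trials per ISI.
#' @param K,I0,alpha Circuit configuration.
#' @param sigma_n Noise intensity.
#' @param seed Master seed.
#' @param isis ISI grid (defaults to [sync_cont_grid()]).
#' @param n_ipis IPIs retained per trial.
#' @param params A [circuit_params()].
#' @return List of class `sync_cont_result`: `mean_ipi` (ISI x k matrix of
#'   mean IPIs), `bias_k` (per-index bias, ms), `isis`, and the raw per-trial
#'   IPI array.
#' @export
run_sync_cont <- function(n_trials_per_isi = 21, K = 2, I0 = 0.77,
                          alpha = 0.05, sigma_n = 0.01, seed = 1,
                          isis = sync_cont_grid(), n_ipis = 20,
                          params = circuit_params()) {
  cfg <- coupled_config(sam_config(K = K, I0 = I0), alpha = alpha)
  arr <- array(NA_real_, c(length(isis), n_trials_per_isi, n_ipis))
  for (ci in seq_along(isis)) {
    sc <- make_sync_cont(isis[ci], start = params$run_in)
    # enough time for 3 + n_continuation productions even at the slow end
    dur <- max(sc$train$onsets) + (sc$n_continuation + 6) * isis[ci]
    for (tr in seq_len(n_trials_per_isi)) {
      sim <- simulate_coupled(params, cfg, sc$train, duration = dur,
                              sigma_n = sigma_n,
                              seed = derive_seed(seed, 10 + ci, tr))
      ip <- diff(sim$production$production_times)
      kk <- min(length(ip), n_ipis)
      if (kk > 0) arr[ci, tr, seq_len(kk)] <- ip[seq_len(kk)]
    }
  }
  mean_ipi <- apply(arr, c(1, 3), mean, na.rm = TRUE)
  structure(list(mean_ipi = mean_ipi,
                 bias_k = bias_by_index(mean_ipi, isis),
                 isis = isis, ipi_array = arr,
                 config = list(n_trials_per_isi = n_trials_per_isi, K = K,
                               I0 = I0, alpha = alpha, sigma_n = sigma_n,
                               seed = seed)),
            class = "sync_cont_result")
}

#' Interval-reproduction task (1-2-Go / 1-2-3-Go)
#'
#' Runs [reproduce_interval()] for each sample interval and trial.
#'
#' @param task `"12go"` (2 flashes) or `"123go"` (3 flashes).
#' @param t_s_values Sample intervals (ms).
#' @param n_trials Trials per sample interval.
#' @param K,I0 SAM configuration.
#' @param sigma_n Noise intensity.
#' @param seed Master seed.
#' @param params A [circuit_params()].
#' @return Data frame with columns `task`, `t_s`, `trial`, `t_p` (`NA` when
#'   no crossing occurred within the guard window).
#' @export
run_reproduction <- function(task = c("12go", "123go"),
                             t_s_values = seq(600, 1000, 100),
                             n_trials = 100, K = 4, I0 = 0.775,
                             sigma_n = 0.01, seed = 1,
                             params = circuit_params()) {
  task <- match.arg(task)
  nf <- if (task == "12go") 2 else 3
  cfg <- sam_config(K = K, I0 = I0)
  out <- expand.grid(t_s = t_s_values, trial = seq_len(n_trials))
  out$t_p <- mapply(function(ts, tr) {
    reproduce_interval(params, cfg, ts, n_flashes = nf, sigma_n = sigma_n,
                       seed = derive_seed(seed, 20 * nf + match(ts, t_s_values), tr))
  }, out$t_s, out$trial)
  cbind(task = task, out)
}
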