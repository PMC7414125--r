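#' Anticipated interval implied by an input level
#'
#' Initializes the SAM at `I0`, presents a single stimulus after the run-in,
#' and returns the interval between that stimulus and the next upward
#' crossing of `y_s` through `y0` - the interval the module "expects" before
#' any update has occurred. Larger `I0` slows the dynamics and lengthens the
#' anticipated interval.
#'
#' @param I0 Input level.
#' @param sigma_n Noise intensity.
#' @param params A [circuit_params()].
#' @param seed Optional RNG seed.
#' @param guard Guard window (ms) after the stimulus.
#' @return Anticipated interval (ms), or `NA` if `y_s` does not cross.
#' @export
anticipated_ts <- function(I0, sigma_n = 0, params = circuit_params(),
                           seed = NULL, guard = 4000) {
  cfg <- sam_config(K = 0, I0 = I0)
  train <- make_isochronous(guard, 1, start = params$run_in)
  sim <- simulate_sam(params, cfg, train, duration = params$run_in + guard,
                      sigma_n = sigma_n, seed = seed)
  cross <- sim$predicted_times[sim$predicted_times > params$run_in]
  if (!length(cross)) return(NA_real_)
  cross[1] - params$run_in
}

# Predicted interval of the SAM after a train of N stimuli at a fixed ISI:
# time from the last stimulus to the next y_s crossing.
sam_predicted_interval <- function(params, cfg, isi, n_stimuli, sigma_n, seed) {
  train <- make_isochronous(isi, n_stimuli, start = params$run_in)
  last <- max(train$onsets)
  sim <- simulate_sam(params, cfg, train, duration = last + 3 * isi,
                      sigma_n = sigma_n, seed = seed, trace = TRUE)
  cross <- anticipation_crossing(sim$trace, after_ms = last, y0 = params$y0)
  if (!is.finite(cross)) return(NA_real_)
  cross - last
}

#' Random-search optimization of the SAM update parameters
#'
#' For a given noise level and number of stimuli, draws candidate pairs
#' (`K`, `I0`) uniformly from their search ranges and evaluates each by the
#' RMSE between the SAM's predicted interval and the true ISI over `n_s`
#' simulated trains whose ISIs are drawn from a five-value discrete uniform
#' distribution between 600 and 1000 ms. The best pair per repeat is
#' recorded; the distribution over repeats summarizes the optimum.
#'
#' @param sigma_n Noise intensity.
#' @param n_stimuli Number of stimuli per train (>= 2).
#' @param n_pairs Candidate pairs per repeat.
#' @param n_repeats Number of repeats.
#' @param n_s Simulated intervals per candidate.
#' @param K_range,I0_range Uniform sampling ranges.
#' @param isi_grid ISI values sampled during evaluation.
#' @param seed Master seed.
#' @param params A [circuit_params()].
#' @return List with `K_star`, `I0_star` (vectors over repeats), their means
#'   and SDs, and the per-repeat candidate tables.
#' @export
optimize_sam <- function(sigma_n, n_stimuli = 3, n_pairs = 100,
                         n_repeats = 10, n_s = 500,
                         K_range = c(1, 8), I0_range = c(0.77, 0.79),
                         isi_grid = seq(600, 1000, 100), seed = 1,
                         params = circuit_params()) {
  stopifnot(n_stimuli >= 2)
  K_star <- I0_star <- numeric(n_repeats)
  tables <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, 100 + rep_i, 0))
    K_c <- stats::runif(n_pairs, K_range[1], K_range[2])
    I0_c <- stats::runif(n_pairs, I0_range[1], I0_range[2])
    isis <- sample(isi_grid, n_s, replace = TRUE)
    obj <- vapply(seq_len(n_pairs), function(ci) {
      cfg <- sam_config(K = K_c[ci], I0 = I0_c[ci])
      pred <- vapply(seq_len(n_s), function(it) {
        sam_predicted_interval(params, cfg, isis[it], n_stimuli, sigma_n,
                               seed = derive_seed(seed, 1000 * rep_i + ci, it))
      }, numeric(1))
      ok <- is.finite(pred)
      if (!any(ok)) return(Inf)
      rmse(pred[ok], isis[ok])
    }, numeric(1))
    best <- which.min(obj)
    K_star[rep_i] <- K_c[best]
    I0_star[rep_i] <- I0_c[best]
    tables[[rep_i]] <- data.frame(K = K_c, I0 = I0_c, rmse = obj)
  }
  list(K_star = K_star, I0_star = I0_star,
       K_mean = mean(K_star), K_sd = sd(K_star),
       I0_mean = mean(I0_star), I0_sd = sd(I0_star),
       candidates = tables, sigma_n = sigma_n, n_stimuli = n_stimuli)
}

# Model-side reproduction summary for a parameter triple: one row per
# (task, t_s) with mean and SD of t_p.
reproduction_summary <- function(K, I0, sigma_n, n_trials, seed,
                                 t_s_values = seq(600, 1000, 100),
                                 params = circuit_params()) {
  out <- list()
  for (task in c("12go", "123go")) {
    d <- run_reproduction(task, t_s_values, n_trials, K = K, I0 = I0,
                          sigma_n = sigma_n, seed = seed, params = params)
    agg <- aggregate(t_p ~ t_s, d, function(x) {
      x <- x[is.finite(x)]
      c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
    })
    out[[task]] <- data.frame(task = task, t_s_ms = agg$t_s,
                              mean_tp_ms = agg$t_p[, "mean"],
                              sd_tp_ms = agg$t_p[, "sd"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Alternating random-search fit of the reproduction model
#'
#' Fits (`sigma_n`, `I0`, `K`) to a per-condition behavioral summary (one
#' mean and SD of `t_p` per sample interval and task, 10 conditions) by
#' alternating two random-search steps: the noise step minimizes the sum of
#' squared SD differences over candidate `sigma_n` values; the input step
#' minimizes the sum of squared mean differences over candidate (`I0`, `K`)
#' pairs. The incumbent parameter set is always included among the
#' candidates, so each step's objective cannot worsen. Candidate evaluations
#' within a step share random numbers (common seeds) to reduce comparison
#' variance.
#'
#' @param subject_summary Data frame with columns `task`, `t_s_ms`,
#'   `mean_tp_ms`, `sd_tp_ms` (10 rows).
#' @param n_samples Candidates per step.
#' @param n_alternations Number of (noise, input) alternations.
#' @param n_trials Trials per condition per candidate.
#' @param K_range,I0_range,sigma_range Uniform sampling ranges.
#' @param seed Master seed.
#' @param params A [circuit_params()].
#' @return A `fit_result` list: `best` (named vector K, I0, sigma_n),
#'   `objective` (final mean-step objective), `history` (per-step objective
#'   values), `candidates` (all sampled candidates with objectives), `seed`.
#' @export
fit_reproduction <- function(subject_summary, n_samples = 100,
                             n_alternations = 3, n_trials = 100,
                             K_range = c(1, 8), I0_range = c(0.77, 0.79),
                             sigma_range = c(0.005, 0.4), seed = 1,
                             params = circuit_params()) {
  req <- c("task", "t_s_ms", "mean_tp_ms", "sd_tp_ms")
  if (!all(req %in% names(subject_summary))) {
    stop("subject summary must have columns ", paste(req, collapse = ", "))
  }
  key <- function(df) paste(df$task, df$t_s_ms)
  subject_summary <- subject_summary[order(key(subject_summary)), ]
  t_s_values <- sort(unique(subject_summary$t_s_ms))

  # start from the middle of the ranges
  cur <- c(K = mean(K_range), I0 = mean(I0_range), sigma_n = mean(sigma_range))
  history <- list()
  all_cand <- list()

  eval_cand <- function(K, I0, sigma_n, step_seed) {
    ms <- reproduction_summary(K, I0, sigma_n, n_trials, step_seed,
                               t_s_values, params)
    ms <- ms[order(key(ms)), ]
    c(obj_sd = sum((ms$sd_tp_ms - subject_summary$sd_tp_ms)^2),
      obj_mean = sum((ms$mean_tp_ms - subject_summary$mean_tp_ms)^2))
  }

  for (alt in seq_len(n_alternations)) {
    # --- noise step: candidates over sigma_n, (I0, K) fixed at incumbent
    set.seed(derive_seed(seed, 200 + alt, 0))
    sig_c <- c(cur["sigma_n"],
               stats::runif(n_samples - 1, sigma_range[1], sigma_range[2]))
    step_seed <- derive_seed(seed, 300 + alt, 0)
    obj <- t(vapply(sig_c, function(s)
      eval_cand(cur["K"], cur["I0"], s, step_seed), numeric(2)))
    best <- which.min(obj[, "obj_sd"])
    cur["sigma_n"] <- sig_c[best]
    history[[length(history) + 1]] <-
      data.frame(alternation = alt, step = "sigma",
                 objective = unname(obj[best, "obj_sd"]))
    all_cand[[length(all_cand) + 1]] <-
      data.frame(alternation = alt, step = "sigma", K = unname(cur["K"]),
                 I0 = unname(cur["I0"]), sigma_n = unname(sig_c), objective = unname(obj[, "obj_sd"]))

    # --- input step: candidates over (I0, K), sigma_n fixed
    set.seed(derive_seed(seed, 400 + alt, 0))
    K_c <- c(cur["K"], stats::runif(n_samples - 1, K_range[1], K_range[2]))
    I0_c <- c(cur["I0"], stats::runif(n_samples - 1, I0_range[1], I0_range[2]))
    step_seed <- derive_seed(seed, 500 + alt, 0)
    obj <- t(vapply(seq_along(K_c), function(ci)
      eval_cand(K_c[ci], I0_c[ci], cur["sigma_n"], step_seed), numeric(2)))
    best <- which.min(obj[, "obj_mean"])
    cur["K"] <- K_c[best]; cur["I0"] <- I0_c[best]
    history[[length(history) + 1]] <-
      data.frame(alternation = alt, step = "mean",
                 objective = unname(obj[best, "obj_mean"]))
    all_cand[[length(all_cand) + 1]] <-
      data.frame(alternation = alt, step = "mean", K = unname(K_c), I0 = unname(I0_c),
                 sigma_n = unname(cur["sigma_n"]), objective = unname(obj[, "obj_mean"]))
  }
  structure(list(best = cur,
                 objective = history[[length(history)]]$objective,
                 history = do.call(rbind, history),
                 candidates = do.call(rbind, all_cand),
                 seed = seed, n_samples = n_samples),
            class = "fit_result")
}

#' Random-search fit of the synchronization/continuation model
#'
#' Fits (`K`, `I0`, `alpha`) to a per-index bias curve (`BIAS_k`,
#' k = 1..20) with `sigma_n` fixed, by uniform random search; the objective
#' is the mean squared error between the candidate's bias curve and the
#' target curve.
#'
#' @param subject_bias Numeric vector of per-index bias values (ms),
#'   k = 1..20.
#' @param n_samples Number of sampled candidates.
#' @param n_trials_per_isi Trials per ISI per candidate.
#' @param K_range,I0_range,alpha_range Uniform sampling ranges.
#' @param sigma_n Fixed noise intensity.
#' @param seed Master seed.
#' @param params A [circuit_params()].
#' @return A `fit_result` list: `best`, `objective`, `candidates`, `seed`.
#' @export
fit_sync_cont <- function(subject_bias, n_samples = 100,
                          n_trials_per_isi = 21,
                          K_range = c(0.01, 5), I0_range = c(0.76, 0.78),
                          alpha_range = c(0.01, 0.1), sigma_n = 0.01,
                          seed = 1, params = circuit_params()) {
  n_k <- length(subject_bias)
  set.seed(derive_seed(seed, 600, 0))
  K_c <- stats::runif(n_samples, K_range[1], K_range[2])
  I0_c <- stats::runif(n_samples, I0_range[1], I0_range[2])
  a_c <- stats::runif(n_samples, alpha_range[1], alpha_range[2])
  obj <- vapply(seq_len(n_samples), function(ci) {
    res <- run_sync_cont(n_trials_per_isi, K = K_c[ci], I0 = I0_c[ci],
                         alpha = a_c[ci], sigma_n = sigma_n,
                         seed = derive_seed(seed, 700, ci), n_ipis = n_k,
                         params = params)
    mean((res$bias_k - subject_bias)^2)
  }, numeric(1))
  best <- which.min(obj)
  structure(list(best = c(K = K_c[best], I0 = I0_c[best], alpha = a_c[best]),
                 objective = obj[best],
                 candidates = data.frame(K = K_c, I0 = I0_c, alpha = a_c,
                                         objective = obj),
                 seed = seed, n_samples = n_samples),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result\n  best:",
      paste(sprintf("%s = %.4g", names(x$best), x$best), collapse = ", "),
      sprintf("\n  objective: %.4g (%d candidates/step)\n",
              x$objective, x$n_samples))
  invisible(x)
}
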