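# Shared, lazily computed simulation runs reused by several tests (the
# tracking protocol is the most expensive harness; two tests inspect the
# same runs from different angles).

.run_cache <- new.env(parent = emptyenv())

# Phases from the variable-ISI blocks (2-5), after the fixed 800 ms lead-in
# block has established synchronization.
late_phases <- function(res, lead_in_ms = 750 + 20 * 800) {
  res$phases[res$phases$stim_ms > lead_in_ms, ]
}

cached_tracking <- function(alpha, n_trials = 80, seed = 7101) {
  key <- paste0("track_a", alpha, "_n", n_trials, "_s", seed)
  if (!exists(key, envir = .run_cache)) {
    assign(key,
           run_tracking(n_trials = n_trials, alpha = alpha, K = 2,
                        I0 = 0.771, sigma_n = 0.01, seed = seed),
           envir = .run_cache)
  }
  get(key, envir = .run_cache)
}
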