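# Independent fine-step reference integrators, written from the model
# equations directly (no calls into the package's simulators). Used as
# oracles for the compiled dt = 10 ms engine.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# One synchronous Euler step of the three-unit module.
oracle_step <- function(u, v, y, I, dt, tau = 100, W = 6,
                        extra_u = 0, extra_v = 0) {
  r <- dt / tau
  c(u + r * (-u + oracle_sigmoid(W * I - W * v + extra_u)),
    v + r * (-v + oracle_sigmoid(W * I - W * u + extra_v)),
    y + r * (-y + u - v))
}

# BCM from standard initial conditions; returns the trajectory matrix and
# the first threshold-crossing time.
oracle_bcm <- function(I, duration, dt = 0.1, y0 = 0.7) {
  n <- round(duration / dt)
  s <- c(0.7, 0.2, 0.5)
  cross <- NA_real_
  traj <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)) {
    y_prev <- s[3]
    s <- oracle_step(s[1], s[2], s[3], I, dt)
    traj[j, ] <- s
    if (is.na(cross) && s[3] >= y0 && y_prev < y0) cross <- j * dt
  }
  list(traj = traj, cross = cross)
}

# MPM with the self-reset pulse (amplitude 50 for 10 ms, beginning the step
# after a crossing); returns production times.
oracle_mpm <- function(I, duration, dt = 0.1, y0 = 0.7, Ip = 50) {
  n <- round(duration / dt)
  ps <- round(10 / dt)
  s <- c(0.7, 0.2, 0.5)
  reset <- 0L
  prod <- numeric(0)
  for (j in seq_len(n)) {
    y_prev <- s[3]
    ra <- reset > 0
    s <- oracle_step(s[1], s[2], s[3], I, dt,
                     extra_u = -Ip * ra, extra_v = Ip * ra)
    if (reset > 0) reset <- reset - 1L
    if (s[3] >= y0 && y_prev < y0) {
      prod <- c(prod, j * dt)
      reset <- ps
    }
    y_prev <- s[3]
  }
  prod
}

# SAM with stimulus resets and the gated input update (frozen during the
# first pulse); returns the final input level and y_s crossing times.
oracle_sam <- function(onsets, K, I0, duration, dt = 0.1, y0 = 0.7, Is = 50) {
  n <- round(duration / dt)
  ps <- round(10 / dt)
  stim <- integer(n)
  for (o in onsets) stim[(round(o / dt) + 1):(round(o / dt) + ps)] <- 1L
  first_end <- round(onsets[1] / dt) + ps
  s <- c(0.7, 0.2, 0.5)
  I <- I0
  cross <- numeric(0)
  for (j in seq_len(n)) {
    y_prev <- s[3]
    sj <- stim[j]
    Keff <- if (j <= first_end) 0 else K
    I_new <- I + (dt / 100) * sj * Keff * (s[3] - y0)
    s <- oracle_step(s[1], s[2], s[3], I, dt,
                     extra_u = -Is * sj, extra_v = Is * sj)
    I <- I_new
    if (s[3] >= y0 && y_prev < y0) cross <- c(cross, j * dt)
  }
  list(I_final = I, cross = cross)
}
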