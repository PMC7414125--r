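test_that("sigmoid is the logistic function with its identities", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-30, -3.42, -1, 0.5, 3.42, 30)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(diff(sigmoid(seq(-10, 10, 0.1))) > 0))
  # high-precision evaluation at the drive used by the default weights
  expect_equal(sigmoid(6 * 0.77 - 6 * 0.2), 1 / (1 + exp(-3.42)),
               tolerance = 1e-12)
  expect_equal(sigmoid(3.42), 0.96832377162094360, tolerance = 1e-10)
})

test_that("draw_noise honours sigma, seed, and the zero case", {
  p <- circuit_params()
  expect_identical(draw_noise(0, 5, p), numeric(5))
  expect_error(draw_noise(-0.1, 5, p))
  set.seed(1); a <- draw_noise(0.01, 1e5, p)
  set.seed(1); b <- draw_noise(0.01, 1e5, p)
  expect_identical(a, b)
  # sample SD close to sigma (3 standard errors of the SD estimate)
  se <- 0.01 / sqrt(2 * (1e5 - 1))
  expect_lt(abs(sd(a) - 0.01), 3 * se)
})

test_that("parameter validation enforces the stated invariants", {
  expect_error(circuit_params(tau = -1))
  expect_error(circuit_params(dt = 0))
  expect_error(circuit_params(dt = 200))       # dt > tau
  expect_error(circuit_params(y0 = 1.2))
  expect_error(circuit_params(pulse_dur = 5))  # < dt
  expect_error(circuit_params(pulse_dur = 15)) # not a multiple of dt
  expect_s3_class(circuit_params(), "circuit_params")
})

test_that("step_bcm preserves symmetry and fixed points", {
  p <- circuit_params()
  # symmetric state with equal weights stays symmetric
  st <- list(u = 0.4, v = 0.4, y = 0)
  st2 <- step_bcm(st, 0.75, p)
  expect_equal(st2$u, st2$v)
  # a self-consistent state is stationary
  I <- 0.75
  u <- v <- NA
  # solve the symmetric fixed point by iteration, then check stationarity
  u <- 0.9; v <- 0.3
  for (i in 1:5000) {
    un <- sigmoid(p$w_uI * I - p$w_uv * v)
    vn <- sigmoid(p$w_vI * I - p$w_vu * u)
    u <- un; v <- vn
  }
  st <- list(u = u, v = v, y = u - v)
  st2 <- step_bcm(st, I, p)
  expect_equal(st2$u, st$u, tolerance = 1e-8)
  expect_equal(st2$v, st$v, tolerance = 1e-8)
  expect_equal(st2$y, st$y, tolerance = 1e-8)
  # hand-computed single Euler step from the standard initial conditions
  expect_equal(step_bcm(list(u = 0.7, v = 0.2, y = 0.5), 0.75, p)$u,
               0.7 + 0.1 * (-0.7 + 1 / (1 + exp(-(6 * 0.75 - 6 * 0.2)))),
               tolerance = 1e-12)
  expect_error(step_bcm(list(u = NaN, v = 0.2, y = 0.5), 0.75, p))
})

test_that("compiled engine reproduces the pure-R step exactly", {
  p <- circuit_params()
  st <- list(u = 0.7, v = 0.2, y = 0.5)
  for (j in 1:100) st <- step_bcm(st, 0.75, p)
  sim <- simulate_bcm(p, 0.75, 100 * p$dt, sigma_n = 0, trace = TRUE)
  expect_equal(sim$trace$u[100], st$u, tolerance = 1e-12)
  expect_equal(sim$trace$v[100], st$v, tolerance = 1e-12)
  expect_equal(sim$trace$y[100], st$y, tolerance = 1e-12)
})

test_that("BCM trajectory and crossing match a fine-step reference", {
  p <- circuit_params()
  orc <- oracle_bcm(0.75, 1000, dt = 0.1)
  sim <- simulate_bcm(p, 0.75, 1000, sigma_n = 0, trace = TRUE)
  # compare at 10 ms marks
  sub <- orc$traj[seq(100, 10000, 100), ]
  expect_lt(max(abs(sim$trace$u - sub[, 1])), 1e-2)
  expect_lt(max(abs(sim$trace$v - sub[, 2])), 1e-2)
  expect_lt(max(abs(sim$trace$y - sub[, 3])), 1e-2)
  expect_lt(abs(sim$first_crossing - orc$cross), p$dt + 1e-9)
})

test_that("larger input delays or prevents the threshold crossing", {
  p <- circuit_params()
  cr <- vapply(c(0.73, 0.75, 0.77), function(I)
    simulate_bcm(p, I, 4000, sigma_n = 0)$first_crossing, numeric(1))
  expect_true(all(diff(cr) > 0))
  expect_true(is.na(simulate_bcm(p, 0.75, 300, sigma_n = 0)$first_crossing))
  # far above the operating range the output never reaches threshold
  expect_true(is.na(simulate_bcm(p, 1.5, 5000, sigma_n = 0)$first_crossing))
})

test_that("unit activities stay within [0, 1] up to integration error", {
  p <- circuit_params()
  eps <- p$dt / p$tau + 1e-9
  for (I in c(0.7, 0.75, 0.78, 0.9)) {
    tr <- simulate_bcm(p, I, 3000, sigma_n = 0, trace = TRUE)$trace
    expect_true(all(tr$u >= -eps & tr$u <= 1 + eps))
    expect_true(all(tr$v >= -eps & tr$v <= 1 + eps))
  }
})

test_that("with u dominant at start the output rises toward threshold", {
  tr <- simulate_bcm(circuit_params(), 0.75, 2000, sigma_n = 0,
                     trace = TRUE)$trace
  # after the initial transient y increases monotonically
  tail_y <- tr$y[20:200]
  expect_true(all(diff(tail_y) > 0))
})

test_that("halving dt changes the zero-noise crossing time by < 2 dt", {
  c10 <- simulate_bcm(circuit_params(dt = 10), 0.75, 2000,
                      sigma_n = 0)$first_crossing
  c5 <- simulate_bcm(circuit_params(dt = 5), 0.75, 2000,
                     sigma_n = 0)$first_crossing
  expect_lt(abs(c10 - c5), 2 * 10)
})

test_that("zero-noise runs are bit-reproducible; seeded runs reproducible", {
  p <- circuit_params()
  a <- simulate_bcm(p, 0.76, 2000, sigma_n = 0, trace = TRUE)
  b <- simulate_bcm(p, 0.76, 2000, sigma_n = 0, trace = TRUE)
  expect_identical(a$trace, b$trace)
  n1 <- simulate_bcm(p, 0.76, 2000, sigma_n = 0.01, seed = 7, trace = TRUE)
  n2 <- simulate_bcm(p, 0.76, 2000, sigma_n = 0.01, seed = 7, trace = TRUE)
  expect_identical(n1$trace, n2$trace)
  expect_false(identical(a$trace$y, n1$trace$y))
})

test_that("noise with non-reference dt triggers the calibration warning", {
  p <- circuit_params(dt = 5)
  expect_warning(simulate_bcm(p, 0.75, 500, sigma_n = 0.01, seed = 1),
                 "dt = 10 ms")
})
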