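test_that("asynchrony and phase follow the nearest-production rule", {
  stim <- stimulus_train(c(1000, 1500, 2000, 2500))
  ap <- asynchrony_phase(c(1000, 1510, 1990), stim)
  expect_equal(ap$asynchrony_ms, c(0, 10, -10))
  expect_equal(ap$phase_deg, c(0, 7.2, -7.2))
  # a=10, ISI=500 -> 7.2 degrees exactly
  expect_equal(ap$phase_deg[2], 360 * 10 / 500)
  # ties break toward the earlier production
  tie <- asynchrony_phase(c(900, 1100, 5000), stimulus_train(c(1000, 2000)))
  expect_equal(tie$prod_ms[1], 900)
  expect_error(asynchrony_phase(numeric(0), stim))
})

test_that("phase wrapping maps onto (-180, 180]", {
  expect_equal(wrap_phase(190), -170)
  expect_equal(wrap_phase(-190), 170)
  expect_equal(wrap_phase(180), 180)
  expect_equal(wrap_phase(-180), 180)  # boundary folded onto +180
  # exhaustive check of the wrapping rule on a fine grid
  phi <- seq(-720, 720, 0.5)
  w <- wrap_phase(phi)
  expect_true(all(w > -180 & w <= 180))
  expect_equal(sin(w * pi / 180), sin(phi * pi / 180), tolerance = 1e-9)
  expect_equal(cos(w * pi / 180), cos(phi * pi / 180), tolerance = 1e-9)
})

test_that("phase and asynchrony are mutually consistent", {
  stim <- make_tracking_blocks(seed = 3)
  sim <- simulate_coupled(circuit_params(),
                          coupled_config(sam_config(), 0.1), stim,
                          sigma_n = 0.01, seed = 4)
  ap <- asynchrony_phase(sim$production, stim)
  raw <- 360 * ap$asynchrony_ms / ap$isi_ms
  expect_equal(wrap_phase(raw), ap$phase_deg)
  # invariant to a global time translation
  stim2 <- stimulus_train(stim$onsets + 12345)
  ap2 <- asynchrony_phase(sim$production$production_times + 12345, stim2)
  expect_equal(ap2$asynchrony_ms, ap$asynchrony_ms)
  expect_equal(ap2$phase_deg, ap$phase_deg)
})

test_that("rmse matches direct summation", {
  expect_equal(rmse(c(800, 800), c(800, 800)), 0)
  expect_equal(rmse(900, 800), 100)
  set.seed(1)
  a <- rnorm(50, 800, 50); b <- rnorm(50, 800, 50)
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 50))
})

test_that("bias and variance decompose the reproduction error", {
  ts <- rep(c(600, 800, 1000), each = 4)
  # constant +50 offset, zero variance
  bv <- bias_var(ts + 50, ts)
  expect_equal(bv$bias2, 2500)
  expect_equal(bv$var, 0)
  # unbiased noiseless
  bv0 <- bias_var(ts, ts)
  expect_equal(bv0$bias2 + bv0$var, 0)
  # random table against a brute-force evaluation
  set.seed(2)
  tp <- ts + rnorm(length(ts), 20, 30)
  bv <- bias_var(tp, ts)
  mns <- tapply(tp, ts, mean)
  vs <- tapply(tp, ts, var)
  expect_equal(bv$bias2, mean((mns - unique(sort(ts)))^2))
  expect_equal(bv$var, mean(vs))
  # decomposition identity: BIAS^2 + VAR equals the MSE about the
  # conditional means plus the squared bias (matched convention, n-1 vs n
  # corrected)
  n_per <- 4
  mse_direct <- mean((tp - ts)^2)
  expect_equal(bv$bias2 + bv$var * (n_per - 1) / n_per, mse_direct,
               tolerance = 1e-9)
})

test_that("per-index bias matches its definition", {
  isis <- c(600, 700, 800)
  m <- rbind(c(600, 650), c(700, 750), c(800, 850))
  expect_equal(bias_by_index(m, isis), c(0, 50))
  # perfect tracking gives zero for all indices
  expect_equal(bias_by_index(cbind(isis, isis), isis), c(0, 0))
  # degenerate single-row table
  expect_equal(bias_by_index(matrix(c(700, 720), 1), 700), c(0, 20))
})

test_that("pythagorean error combines its two arguments symmetrically", {
  expect_equal(pythagorean_error(0, 0), 0)
  expect_equal(pythagorean_error(30, 40), 50)
  expect_equal(pythagorean_error(40, 30), 50)
})

test_that("Rayleigh test separates concentrated from uniform phases", {
  conc <- rayleigh_test(rep(15, 50))
  expect_equal(conc$R, 1)
  expect_lt(conc$p, 1e-10)
  expect_equal(conc$mean_deg, 15)
  unif <- rayleigh_test(seq(-179, 180, 1))
  expect_lt(unif$R, 1e-10)
  expect_gt(unif$p, 0.99)
  expect_error(rayleigh_test(c(1, 2, 3)))
})

test_that("Rayleigh test has approximately nominal type-I error", {
  set.seed(8)
  rejections <- vapply(1:400, function(i) {
    ph <- stats::runif(150, -180, 180)
    rayleigh_test(ph)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  # 3 binomial SEs around 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("circular SD follows sqrt(-2 log R)", {
  ph <- c(-30, 0, 30)
  cs <- circular_stats(ph)
  expect_equal(cs$sd_deg, sqrt(-2 * log(cs$R)) * 180 / pi)
  expect_equal(cs$mean_deg, 0, tolerance = 1e-9)
})

test_that("linear regression summary agrees with the normal equations", {
  x <- 1:20
  expect_equal(linear_fit_r2(x, 2 * x)$r2, 1)
  expect_equal(linear_fit_r2(x, rep(3, 20))$r2, 0)
  set.seed(3)
  y <- 1.5 * x + rnorm(20)
  f <- linear_fit_r2(x, y)
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(f$slope, b)
  expect_equal(f$intercept, a)
  expect_equal(f$r2, r2)
})
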