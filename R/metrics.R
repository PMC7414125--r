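#' Asynchrony and phase of productions relative to stimuli
#'
#' For every stimulus onset `m_n` the production closest in time is found
#' (ties broken toward the earlier production) and the asynchrony
#' `a_n = t_n - m_n` computed; negative values mean the action led the
#' stimulus. The phase is `phi_n = 360 * a_n / ISI_n` (degrees), where
#' `ISI_n` is the interval following stimulus `n`, wrapped to (-180, 180].
#' Stimuli without a following interval are dropped. Several stimuli may
#' share one production (skipped beats); the number of such stimuli is
#' reported.
#'
#' @param productions Production times (ms) or a [production_record()].
#' @param stimuli A [stimulus_train()].
#' @return A data frame with columns `stim_ms`, `prod_ms`, `asynchrony_ms`,
#'   `isi_ms`, `phase_deg`; attribute `n_shared` counts stimuli matched to a
#'   production that also serves another stimulus.
#' @export
asynchrony_phase <- function(productions, stimuli) {
  if (inherits(productions, "production_record")) {
    productions <- productions$production_times
  }
  stopifnot(inherits(stimuli, "stimulus_train"))
  if (!length(productions) || length(stimuli$onsets) < 2) {
    stop("need at least one production and two stimuli")
  }
  m <- stimuli$onsets[-length(stimuli$onsets)]
  isi <- stimuli$isis
  idx <- vapply(m, function(mn) {
    d <- abs(productions - mn)
    which(d == min(d))[1]            # earlier production on ties
  }, integer(1))
  a <- productions[idx] - m
  phi <- wrap_phase(360 * a / isi)
  out <- data.frame(stim_ms = m, prod_ms = productions[idx],
                    asynchrony_ms = a, isi_ms = isi, phase_deg = phi)
  attr(out, "n_shared") <- sum(duplicated(idx) | duplicated(idx, fromLast = TRUE))
  out
}

#' Wrap phases to (-180, 180]
#'
#' @param phi_deg Phases in degrees.
#' @return Wrapped phases.
#' @export
wrap_phase <- function(phi_deg) {
  w <- phi_deg %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Root-mean-squared error between produced and target intervals
#'
#' @param ipis Produced intervals (ms).
#' @param isis Target intervals (ms), recycled if scalar.
#' @return RMSE in ms.
#' @examples
#' rmse(900, 800) # 100
#' @export
rmse <- function(ipis, isis) {
  stopifnot(length(ipis) > 0)
  sqrt(mean((ipis - isis)^2))
}

#' BIAS^2 and VAR decomposition of interval reproduction
#'
#' For productions grouped by target interval, `BIAS^2` is the mean squared
#' deviation of the per-target mean production from the target, and `VAR` is
#' the mean per-target variance (computed with the n-1 denominator). Their
#' sum approximates the overall mean squared error.
#'
#' @param tp Produced intervals (ms).
#' @param ts Target interval of each production (ms).
#' @return List with `bias2`, `var`, `bias` (= sqrt(bias2)) and the
#'   per-target table `by_ts`.
#' @export
bias_var <- function(tp, ts) {
  stopifnot(length(tp) == length(ts))
  keep <- is.finite(tp)
  tp <- tp[keep]; ts <- ts[keep]
  tab <- aggregate(tp, list(ts = ts),
                   function(x) c(mean = mean(x),
                                 var = if (length(x) > 1) var(x) else 0))
  m <- tab$x[, "mean"]; v <- tab$x[, "var"]
  bias2 <- mean((m - tab$ts)^2)
  list(bias2 = bias2, var = mean(v), bias = sqrt(bias2),
       by_ts = data.frame(ts = tab$ts, mean_tp = m, var_tp = v))
}

#' Per-index squared bias of interval sequences
#'
#' For a matrix of mean produced intervals (rows = target ISIs, columns =
#' interval index k in the sequence), computes
#' `BIAS_k^2 = mean_i (mean_IPI[i, k] - ISI_i)^2`.
#'
#' @param mean_ipi Matrix of per-ISI mean IPIs (rows follow `isis`).
#' @param isis Target ISI of each row (ms).
#' @return Numeric vector `bias_k` (ms), the positive square root of
#'   `BIAS_k^2`, one entry per column.
#' @export
bias_by_index <- function(mean_ipi, isis) {
  mean_ipi <- as.matrix(mean_ipi)
  stopifnot(nrow(mean_ipi) == length(isis))
  unname(sqrt(colMeans((mean_ipi - isis)^2, na.rm = TRUE)))
}

#' Combined timing error
#'
#' Euclidean combination of the interval error and the asynchrony,
#' `sqrt((IPI - ISI)^2 + a^2)`.
#'
#' @param ipi_err Interval error (ms).
#' @param asynchrony Asynchrony (ms).
#' @return Combined error (ms).
#' @examples
#' pythagorean_error(30, 40) # 50
#' @export
pythagorean_error <- function(ipi_err, asynchrony) {
  sqrt(ipi_err^2 + asynchrony^2)
}

#' Circular mean, resultant length and circular SD of phases
#'
#' @param phases_deg Phases in degrees.
#' @return List with `mean_deg`, `R` (mean resultant length) and `sd_deg`
#'   (`sqrt(-2 log R)` in degrees).
#' @export
circular_stats <- function(phases_deg) {
  rad <- phases_deg * pi / 180
  S <- mean(sin(rad)); C <- mean(cos(rad))
  R <- sqrt(S^2 + C^2)
  list(mean_deg = atan2(S, C) * 180 / pi, R = R,
       sd_deg = sqrt(-2 * log(R)) * 180 / pi)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that phases are uniformly distributed on the
#' circle, using the standard approximation to the distribution of the
#' resultant length.
#'
#' @param phases_deg Phases in degrees (n >= 5).
#' @return List with `R` (mean resultant length), `p`, `mean_deg`, `sd_deg`
#'   and `n`.
#' @export
rayleigh_test <- function(phases_deg) {
  n <- length(phases_deg)
  if (n < 5) stop("Rayleigh test requires at least 5 phases")
  cs <- circular_stats(phases_deg)
  z <- n * cs$R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(R = cs$R, p = p, mean_deg = cs$mean_deg, sd_deg = cs$sd_deg, n = n)
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' coefficient of determination, F statistic and p value.
#'
#' @param x,y Numeric vectors.
#' @return List with `slope`, `intercept`, `r2`, `F`, `df`, `p`.
#' @export
linear_fit_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 2)
  if (var(y) == 0) {
    return(list(slope = 0, intercept = y[1], r2 = 0, F = 0,
                df = c(1, length(x) - 2), p = 1))
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  Fv <- if (sm$r.squared >= 1) Inf else sm$fstatistic[["value"]]
  df2 <- length(x) - 2
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, F = Fv, df = c(1, df2),
       p = if (is.infinite(Fv)) 0 else pf(Fv, 1, df2, lower.tail = FALSE))
}
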