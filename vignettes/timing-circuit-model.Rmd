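---
title: "A modular rate-unit circuit for sensorimotor timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A modular rate-unit circuit for sensorimotor timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronocircuit)
```

## The model

The package simulates a small dynamical system for human sensorimotor
timing. Its building block is a three-unit module: two rate units $u$ and
$v$ inhibit one another, receive a shared tonic input $I$, and drive an
output unit $y$ with excitatory and inhibitory connections:

$$
\tau \dot u = -u + \theta(W_{uI} I - W_{uv} v + \eta_u), \qquad
\tau \dot v = -v + \theta(W_{vI} I - W_{vu} u + \eta_v), \qquad
\tau \dot y = -y + W_{yu} u - W_{yv} v + \eta_y,
$$

with $\theta(x) = 1/(1+e^{-x})$. With the default symmetric weights
($W = 6$ for input and mutual inhibition, unit output weights) the system
has two stable fixed points (one with $u$ dominant, one with $v$ dominant)
separated by a saddle on the diagonal. Started from the $u$-dominant basin
($u = 0.7$, $v = 0.2$, $y = 0.5$), the state relaxes toward the
$u$-dominant fixed point and $y$ ramps toward the movement-initiation
threshold $y_0 = 0.7$. The tonic input sets the position of the nullclines
and hence the ramp speed: larger $I$ means a slower approach and a later
threshold crossing, which is how a scalar input encodes a target interval.

Two module variants reuse these dynamics:

* the **motor planning module (MPM)** registers a production whenever
  $y_p$ crosses $y_0$ and then delivers a brief reset pulse $I_p = 50$
  (negative to $u_p$, positive to $v_p$, inside the sigmoid arguments) for
  one pulse duration, after which the ramp restarts — periodic production;
* the **sensory anticipation module (SAM)** receives the same pulse from
  *stimuli* ($s I_s$, $s \in \{0, 1\}$) and never resets itself. While a
  stimulus is on, the shared input integrates the anticipation error,
  $\tau \dot I = s K (y_s - y_0)$: if $y_s$ is still below threshold when
  a stimulus arrives the interval was overestimated and $I$ decreases
  (speeding the next ramp); if $y_s$ is already above, $I$ increases. The
  update is frozen during the first stimulus of a run, before any interval
  has been observed.

The full model couples the two: they share $I$ (updated only by the SAM),
and a phase-correction pathway augments the MPM's drive with
$\Delta I = \alpha (y_p - y_s)$, recomputed from the current state at every
step. When the MPM lags the SAM ($y_s > y_p$), $\Delta I < 0$ and the MPM
speeds up; when it leads, it is slowed. $\alpha = 0$ removes the pathway
exactly.

An important and perhaps counterintuitive property of the reset is that it
is *partial*. One 10 ms pulse at amplitude 50 saturates the sigmoid
arguments, but the units relax with $\tau = 100$ ms, so a single-step pulse
moves $u, v$ only about 10% of the way toward the saturated configuration.
This is by design: a pulse long enough to complete the excursion would push
the state across the saddle into the $v$-dominant basin, from which no
further ramps (and hence no further productions) occur. The operating
regime therefore lives on partial kicks whose recovery time — the
timed interval — is controlled by $I$.

## Numerical scheme

All simulations use synchronous forward-Euler integration: every
derivative is evaluated at the current state, then all units (including
$I$ and $\Delta I$) advance together. The reference step is
$\mathrm{d}t = 10$ ms; pulses last exactly one step; threshold crossings
are detected after a full step as $y \ge y_0$ with $y < y_0$ at the
previous step, reported at step resolution without sub-step interpolation.
Euler integration is first-order: halving the step changes zero-noise
crossing times by less than two coarse steps, and the test suite checks
trajectories and crossing times against an independent $\mathrm{d}t =
0.1$ ms integrator. Because the late approach to threshold is very flat
(the $u - v$ asymptote sits only a few thousandths above $y_0$ in the
operating range), crossing times at the slow end of the input range are
intrinsically the most step-size- and noise-sensitive quantities in the
model.

The noise terms $\eta$ are zero-mean Gaussian draws, independent per unit
and per step, with standard deviation $\sigma_n$ defined *per step at the
reference step size*. No $\sqrt{\mathrm{d}t}$ rescaling is applied;
simulating with a different step while $\sigma_n > 0$ changes the
effective noise process, and the simulators warn in that case. $\eta_u$
and $\eta_v$ enter inside their sigmoid arguments (where the sigmoid slope
attenuates them), while $\eta_y$ adds directly to the output drive and
dominates the variability of threshold crossings.

One readout subtlety: $y_s$ follows $u_s - v_s$ with lag $\tau$, so when a
flash arrives close to the currently anticipated interval, $y_s$ can still
be rising through $y_0$ for a step or two *after* the reset has begun. The
anticipated-interval readout therefore counts a crossing only after $y_s$
has dropped below threshold following the final flash; without this rule
the deterministic map from sample interval to produced interval shows
isolated 10 ms collapses wherever the flash lands on an unreturned
crossing.

## Task protocols

The generators in `make_*()` implement the study conditions:

* **Periodic production**: MPM alone, 40 s at each input level in
  $\{0.75, 0.76, 0.77, 0.78\}$, $\sigma_n = 0.01$, first 40 intervals per
  level.
* **ISI tracking**: coupled circuit; per trial, one block of twenty
  800 ms intervals followed by four blocks of twenty intervals whose ISI
  is drawn from $\{600, 700, 800, 900\}$ ms (independent draws, repeats
  allowed); $K = 2$, $I_0 = 0.771$, $\sigma_n = 0.01$, $\alpha \in \{0,
  0.1\}$.
* **Perturbations**: thirty unperturbed intervals, then a step change
  (800 to 1000 ms), a phase shift (one 600 ms interval in a 500 ms
  stream), or a jitter (600 then 400 ms, returning to the original grid);
  $\sigma_n = 0.005$.
* **Interval reproduction (1-2-Go / 1-2-3-Go)**: SAM alone; two or three
  flashes separated by a sample interval from $\{600, \ldots, 1000\}$ ms;
  the produced interval runs from the final flash to the next anticipated
  crossing; 100 trials per condition.
* **Synchronization/continuation**: three flashes at an ISI from the
  five-point grid 550-817 ms, then 17 free productions;
  21 trials per ISI, $\sigma_n = 0.01$. The grid's interior values are not
  printed in the protocol we follow; we use the evenly spaced values
  `r paste(sync_cont_grid(), collapse = ", ")` ms and expose the grid as an
  argument.

Every harness derives per-trial seeds with a counter-based scheme
(`derive_seed()`), so runs are reproducible from a single master seed and
adding trials never changes earlier ones.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| $\tau$ | 100 ms | relaxation time of all units |
| $W$ | 6 | input and mutual-inhibition weights (symmetric) |
| $y_0$ | 0.7 | initiation/anticipation threshold |
| $I_p$, $I_s$ | 50 | reset/stimulus pulse amplitudes (saturating) |
| $I_0$ | task-specific | initial input = prior expectation of the interval |
| $K$ | task-specific | anticipation-error gain on the input update |
| $\alpha$ | 0-0.15 | phase-correction gain |
| $\sigma_n$ | 0.005-0.05 | per-step noise SD |

$I_0$ acts as the model's prior: before any update, it alone sets the
produced/anticipated interval (`anticipated_ts()`). $K$ trades speed of
interval learning against noise sensitivity — the random-search
optimization (`optimize_sam()`) shows the optimal $K$ falling as noise or
the number of integrated stimuli grows, while the optimal $I_0$ barely
moves. $\alpha$ trades phase alignment against rhythm stability: the
combined interval-plus-asynchrony error is U-shaped in $\alpha$ with its
minimum near 0.1.

For the reproduction tasks the defaults ($K = 4$, $I_0 = 0.775$,
$\sigma_n = 0.01$) were chosen once as a configuration in which the mean
produced interval is monotone in the sample interval across the full
600-1000 ms range while clearly expressing the central-tendency bias;
smaller gains or higher starting inputs push the long-interval conditions
into the near-critical regime where the input ceiling compresses the top
of the map.

One printed calibration did not reproduce: with these equations and
integration conventions, $I_0 = 0.771$ yields a deterministic period of
720 ms rather than the 800 ms the tracking protocol's calibration
describes; plausible alternative reset conventions bracket 800 ms (930 ms
for a two-step pulse) without hitting it. We keep the printed value and
the one-step convention; the consequence is a slightly faster starting
tempo in the tracking task and somewhat weaker anticipation-error signals
than the original implementation appears to have had.

## Analysis conventions

Productions are matched to stimuli per stimulus, by the closest production
in time (ties to the earlier production; several stimuli may share a
production when a beat is skipped). The phase of a production is its
asynchrony normalized by the interval that follows its stimulus, in
degrees, wrapped to $(-180, 180]$.

Two conventions deserve explanation:

* **Tracking $r^2$.** The headline statistic is the *mean within-trial*
  coefficient of determination of the index-paired sequences (the $n$th
  produced interval against the $n$th stimulus interval), reported by
  `analyze_tracking()` alongside the pooled-pairs and trial-mean
  regressions. Within a trial the shared input wanders slowly under noise;
  the within-trial statistic summarizes how lawfully production follows
  stimulation in a single run of the protocol.
* **Phase uniformity.** Consecutive phases within a trial are serially
  dependent — without phase correction the phase performs a random walk —
  so a pooled Rayleigh test across thousands of correlated phases
  overstates the evidence wildly. Uniformity is therefore tested on
  per-trial circular means (one independent value per run), computed after
  the fixed 800 ms lead-in block has established synchronization. With the
  pathway on the per-trial means concentrate tightly (test rejects,
  $p \ll 0.01$); with it off they spread over the circle (test does not
  reject).

The reproduction error decomposes into `bias_var()`'s BIAS$^2$ (squared
deviation of per-condition means from their targets) and VAR (mean
per-condition variance, $n-1$ denominator); the per-index bias of
synchronization/continuation sequences is the root mean squared deviation
of per-ISI mean intervals from their ISIs at each sequence position.

## The linear baseline

`linear_params()` and its simulators implement the standard
error-correction algorithm: $t_{n+1} = t_n + T_n - \beta_{\mathrm{as}}
(t_n - m_n) - \beta_{\mathrm{ISI}} (T_n - \mathrm{ISI}_n) + \eta$, with
the interval estimate tracking the observed interval exponentially,
$T_{n+1} = T_n - \beta_{\mathrm{ISI}} (T_n - \mathrm{ISI}_n)$ (the
recursion for $T$ is our reading; the update rule fixes only the
production times). In reproduction the estimate shrinks geometrically
toward the sample, $(1 - \beta)^{n}$ per observation — a closed form the
tests exploit. In synchronization/continuation the estimate freezes at its
value at the last stimulus, so continuation intervals have a constant mean
and the per-index continuation bias is flat. The circuit model, in
contrast, keeps integrating its negative $\Delta I$ during continuation
(the un-reset SAM output settles above threshold), which shortens
intervals, flattens the interval-vs-ISI slope, and *raises* the bias after
the stimulus stops — the key qualitative contrast between the two model
classes.

## What the synthetic data do and do not show

`generate_fixture_subject()` produces behavioral summary tables by
simulating the circuit itself at known parameters; the fitting procedures
(`fit_reproduction()`, alternating random search over $\sigma_n$ and
$(I_0, K)$ with the incumbent always among the candidates and common
random numbers within a step; `fit_sync_cont()`, random search over
$(K, I_0, \alpha)$) are validated by parameter recovery against these
self-generated targets. Passing recovery shows the objectives identify the
generating parameters under the model's own noise; it does not show the
model fits *human* data, whose lapses, drifts and motor delays the
generator does not emulate. Likewise the stimulus generators idealize the
human protocols: flashes are 10 ms events on the integration grid, there
are no warning cues, feedback, or discarded lapse trials.

## Known limitations

* Quantities tied to the flat late approach to threshold (long-interval
  crossing times, the top of the reproduction map) are the most sensitive
  to step size, noise level and reset conventions; reported statistics
  involving them carry a few percent of implementation dependence.
* The residual concentration of production phases without phase correction
  (resultant length about 0.1) is nonzero; the protocol's shared structure
  across trials leaves a trace that per-trial aggregation, not pooling,
  must absorb.
* No attempt is made to model motor execution delays between threshold
  crossing and overt action, spiking dynamics, or learning of the prior
  itself.

## Problem sizes used by the tests

The test suite runs the full protocols at moderate sizes chosen to make
the checked contrasts statistically stable: 80 tracking trials per
pathway setting, 150 perturbation trials per kind, 100 reproduction trials
per condition, 21 synchronization/continuation trials per ISI, and
scaled-down random searches (20-50 candidates, 30-100 evaluations per
candidate) for the fitting and optimization trend checks. The acceptance
script uses 100-250 tracking trials for its reported statistics.
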