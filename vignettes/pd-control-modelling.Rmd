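---
title: "PD control modelling of a stop-sign driving task: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PD control modelling of a stop-sign driving task: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrive)
```

## The task and its model

The task records a participant driving a simulated car in one dimension
from a start line to a stop sign, then holding position, for about 10
seconds per trial, with position and velocity sampled at every frame
(~60 Hz). Sessions consist of two blocks of 10 trials; a trial is
restarted (and counted as an error) if the car leaves the screen, input
is lost, or the car does not end near the sign.

We model acceleration as proportional–derivative feedback on the goal
error $e_t = g - x_t$:

$$\ddot{x}_t = K_p e_t - K_d \dot{x}_t + \varepsilon_t,
\qquad \varepsilon_t \sim \mathcal{N}(0, \sigma^2).$$

$K_p$ (1/s²) drives the car toward the sign; $K_d$ (1/s) brakes in
proportion to speed. Writing $u = x - g$, the noiseless system is a
damped harmonic oscillator with natural frequency $\sqrt{K_p}$ and
damping ratio $\zeta = K_d / (2\sqrt{K_p})$; $\zeta < 1$ predicts
overshoot of the sign, $\zeta \ge 1$ precludes it. The model's key
assumptions: control is linear in error and velocity, gains are constant
within a trial, and disturbance enters as white noise on acceleration.

### Coordinates and constants

Positions are normalized so the start is 0 and the stop sign is at the
track length, 1 by default. The task's one stated physical constant is
that a car at maximum speed traverses the track in 0.75 s, so the
default speed cap is `track_length / 0.75`. Defaults:
`sample_rate = 60` Hz, `trial_duration = 10` s (600 samples),
`goal_tolerance = 0.05`, `offscreen_limit = 0.5` past the sign.

## Estimation

Acceleration is not recorded; we derive it by forward differences of
recorded velocity, $a_i = (v_{i+1} - v_i)/(t_{i+1} - t_i)$, aligned to
the left sample. We difference velocity rather than twice-difference
position because each differencing pass amplifies measurement noise.
Per trial we then fit, with no intercept,

$$a_i = K_p e_i + K_d (-v_i) + \text{residual},$$

by ordinary least squares; the two coefficients are the gain estimates.
A fit is marked invalid — with a reason code, never an exception that
aborts a cohort run — when the design is rank-deficient, the trajectory
is degenerate (parked at the goal throughout), or either coefficient is
non-positive, since downstream analyses use natural logs of the gains.
Natural logs (not base 10) are the package convention; the base only
shifts the scale of every downstream statistic's inputs uniformly.
Error-terminated trials are excluded from fitting — their truncated
dynamics reflect an aborted attempt — but they feed the error-count
behavioral index, whose log uses $\log(\text{count} + 1)$ so zero-error
subjects are defined.

By default the full 10-s trace is fitted, including the long parked tail
at the sign. The tail is nearly uninformative for the gains (error and
velocity both near zero) but harmless under the model; a configurable
post-stop truncation (`truncate_post_stop`) drops samples after the car
has settled within the goal tolerance at negligible speed, for users who
want to fit only the approach.

Fit quality is summarized by re-simulating the trial noiselessly from
its recorded starting conditions with the fitted gains and computing
$R^2 = 1 - SS_{res}/SS_{tot}$ between predicted and observed velocity
over all frames. This is deliberately harsher than in-sample regression
$R^2$: errors compound through the forward simulation, and the value can
be negative when the simulation predicts velocity worse than its mean.

## Numerical choices

**Integration.** The simulator uses explicit Euler at the task's own
frame rate: the state recorded at frame $i$ is the state before that
frame's update, and
$x_{i+1} = x_i + v_i \Delta t$, $v_{i+1} = v_i + a_i \Delta t$ with
$a_i$ evaluated at the recorded state. This makes the generator the
exact inverse of the estimator — forward differences of simulated
velocity return $a_i$ identically — so noiseless fits recover generating
gains to machine precision at any frame rate, and under acceleration
noise the regression is correctly specified. A step is flagged with a
warning when the Euler update's spectral radius exceeds 1 (divergent
discretization).

**Integrator accuracy.** Euler is first-order: against the analytic
damped-oscillator solution (`closed_form_trajectory`, with under-,
critically- and over-damped branches selected by the sign of
$K_d^2 - 4K_p$), the maximum position error falls ~10× for every 10×
increase in sample rate. At 600 Hz the error is below $10^{-3}$ track
lengths for well-damped moderate gains but reaches $5 \times 10^{-3}$
at the fastest, least-damped corner we test ($K_p = 25$,
$\zeta = 0.3$). We accept this: a second-order integrator (Heun) cuts
the 600 Hz error to $10^{-5}$, but we measured that pairing it with any
finite-difference acceleration estimate breaks the estimator — forward
differences acquire a ~17% systematic error, and central differences,
though accurate noiselessly, correlate the regressors with the
response's noise increments and attenuate $\hat{K}_p$ by ~18% at
realistic noise. Faithful, unbiased estimation matters more here than
the generator's ODE accuracy at extreme gains, because estimation is
what the package exists to study.

**Finite-sample bias of closed-loop least squares.** Even with the
exactly specified Euler regression, the regressors are functions of past
noise (the system is in feedback), so plain least squares is consistent
but not exactly unbiased in finite samples — the same phenomenon as
autoregression bias. Over 2,000 replicates of a 600-sample trial at
$K_p = 8$, $K_d = 5$, the relative bias of $\hat{K}_p$ is ~0.1% at
$\sigma = 0.5$, ~0.5% at $\sigma = 1$, ~1.5% at $\sigma = 2$ and ~2.9%
at the cohort default $\sigma = 3.5$ — small against the ~13%
trial-to-trial sampling spread, and diluted further by 20-trial session
means, but real. Unbiasedness checks in the test suite therefore run in
the clean-trial regime ($\sigma = 1$); a separate test bounds the
relative bias at cohort noise below 5%.

**Velocity clipping.** A cap at the task's maximum speed is available in
the simulator but off by default, and default gain ranges are chosen so
it would not engage: saturated samples violate the linear model and
would bias fits, and the estimation stage assumes no saturation
handling.

## Reliability statistics

Split-half reliability correlates, across subjects, mean log gains from
two disjoint halves of a session's valid trials. Two schemes: odd/even
trial parity, and first/second half of the session (with an odd count,
the middle trial joins the first half — a convention required because
error trials make counts uneven). Session comparisons use Fisher's z:
$z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$, two-sided normal p.

Test–retest reliability across sessions is ICC(3,1) — two-way mixed,
consistency, single fixed rater — computed from the two-way ANOVA mean
squares: $(MS_{subjects} - MS_{error}) / (MS_{subjects} + MS_{error})$
for two sessions. Consistency means a constant session shift (e.g.
practice effects moving everyone equally) does not reduce the
coefficient. The p-value is the one-sided F test of
$MS_{subjects}/MS_{error}$, the standard test against ICC = 0. Under a
stable trait with independent estimate noise, the expected split-half r
equals true-score variance over total variance (the Spearman–Brown
relation), and the pipeline's ICC converges to the true across-session
correlation of subject parameters as estimate noise vanishes — both are
verified as tests.

Exclusion toggles (same-day completers, non-mobile devices) mirror the
sensitivity analyses a validation study of a mobile task needs.

## Association models

Each outcome (mean log $K_p$, mean log $K_d$, mean final car position,
log error-trial count) is regressed on fear, age, male gender and
bachelor's-or-higher education; demographics-only variants drop fear.
All variables — binaries included — are z-scored before fitting, so
coefficients are standardized betas and, with a single predictor, equal
the Pearson correlation. Z-scoring binaries is a deliberate convention
(it makes all betas comparable on the same scale); users comparing
against partial-standardization conventions should rescale accordingly.
Missing covariates are handled by listwise deletion, and no
multiple-testing correction is applied, with the number of fitted models
reported alongside the results. Final car position is averaged across
valid trials within a session.

## The synthetic-data generator

`cohort_spec()` + `simulate_cohort()` generate cohorts with known truth.
The generative structure, per subject:

* Covariates: PANAS-X fear (truncated normal, mean 10.5, sd 3.5 on the
  6–30 range of a 6-item 1–5 scale), age 35.8 ± 9.5 (truncated at 18),
  64% male, 79% bachelor's-or-higher, 90% mobile-device, 10% same-day —
  rates a remote-recruitment validation cohort plausibly exhibits.
* True log gains: each session's standardized log gain is
  $\beta_f z_{fear} + \sqrt{1-\beta_f^2}\,\eta$, where the residual
  $\eta$ shares a subject-level component sized so the across-session
  correlation of the gain equals `session_correlation` exactly, and
  within-session residuals of the two gains correlate at
  `param_correlation` (exactly when the two planted effects are equal,
  approximately otherwise). This requires
  `session_correlation` $\ge \beta_f^2$; impossible combinations raise
  an error rather than silently renormalizing. Defaults:
  log $K_p \sim \mathcal{N}(\log 8, 0.5)$,
  log $K_d \sim \mathcal{N}(\log 5, 0.5)$ (median damping ratio ~0.9,
  mild overshoot — the behaviour the task actually elicits),
  session correlation 0.85, parameter correlation 0.3, fear effects
  −0.29 on both log gains.
* Trials: per-trial gains jitter around the subject-session mean with
  sd 0.35 on the log scale (people do not reuse identical control
  policies), plus acceleration noise sd 3.5. Error trials occur at rate
  0.05 and are truncated at a uniform frame at least half a second in —
  only their count feeds analysis, so re-simulating restarts would add
  nothing.
* All draws flow from one seed through named substreams (cohort,
  trial-params, noise, error-trials), so stages are independently
  reproducible and bit-identical across runs.

These defaults were chosen once, as the package's picture of a realistic
cohort: they yield mean simulation $R^2 \approx 0.74$ (sd 0.15),
split-half r ≈ 0.92–0.96 and ICC ≈ 0.79–0.87 at n = 100 — the regime a
dense-sampling motor task occupies, unusually high for a behavioral
measure precisely because each trial contributes ~600 samples. A default
cohort (100 subjects × 2 sessions × 20 trials ≈ 4,000 trajectories)
generates and fits in well under a minute; the test suite uses smaller
cohorts (12–80 subjects, 4–10 trials) chosen to keep each check's
Monte-Carlo error far below the effect it verifies.

**What the generator does not emulate.** Frame-rate jitter and dropped
frames; touch-dynamics and device heterogeneity (beyond a binary
mobile flag); velocity saturation; within-trial gain drift; non-normal
subject distributions beyond log-normality; practice effects (sessions
differ only by resampled residuals). Passing tests therefore show the
machinery is correct under the stated model, not that the model captures
every property of human data — on real trajectories, the simulation
$R^2$ distribution and the validity-flag rates are the first diagnostics
to inspect.

## Degenerate inputs and tie-breaks

* Trials with fewer than 3 samples, duplicate time stamps, a parked-car
  degenerate trace, rank-deficient designs or non-positive coefficients:
  invalid fit with reason code; the cohort run continues.
* Subject-session cells with zero valid trials: summary row kept,
  flagged missing, excluded from reliability/association.
* Reliability with fewer than 4 subjects (or ICC with fewer than 5
  pairs): the stage is skipped with an explicit notice, not a crash.
* `|r| = 1` in Fisher's z: infinite transform, reported as such with a
  warning.
* Association models with zero-variance columns (e.g. error counts in an
  error-free cohort): that model is skipped and diagnosed; the run fails
  only if every model fails.

## Known limitations

* The estimator's finite-sample bias at high noise (above) — negligible
  at session level, but visible in single-trial Monte-Carlo studies.
* Explicit Euler's first-order error against the continuous ODE at
  fast, lightly damped gains (above); irrelevant to estimation, which
  inverts the discrete system exactly, but worth knowing if trajectories
  are compared against analytic solutions.
* ICC p-values assume the standard two-way ANOVA F distribution; with
  heavy-tailed subject effects they are approximate.
* The trace report averages velocity across trials frame-by-frame from
  trial start; it does not time-align trials on movement onset.
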