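#' Construct a single-trial trajectory object
#'
#' A `trial_trajectory` holds one trial's frame-sampled time series (time,
#' position, velocity) together with its identifiers and termination
#' status. Invariants are checked: equal-length series and strictly
#' increasing time stamps starting at 0.
#'
#' @param t Time stamps in seconds, strictly increasing, starting at 0.
#' @param position Car position per sample (track units).
#' @param velocity Car velocity per sample (track units/s).
#' @param subject_id Opaque subject identifier.
#' @param session Session number, 1 or 2.
#' @param block Block number, 1 or 2.
#' @param trial_index Trial number within the session, >= 1.
#' @param terminated_with_error Logical: did the trial end in an error
#'   (off-screen, not stopped at the sign, input lost)?
#' @param restart_count Number of restarts recorded for this trial slot.
#' @return An object of class `trial_trajectory`.
#' @export
trial_trajectory <- function(t, position, velocity,
                             subject_id = "s1", session = 1L, block = 1L,
                             trial_index = 1L,
                             terminated_with_error = FALSE,
                             restart_count = 0L) {
  n <- length(t)
  if (length(position) != n || length(velocity) != n) {
    stop("t, position and velocity must have equal length", call. = FALSE)
  }
  if (n > 1 && any(diff(t) <= 0)) {
    stop("time stamps must be strictly increasing", call. = FALSE)
  }
  if (trial_index < 1) stop("trial_index must be >= 1", call. = FALSE)
  if (restart_count < 0) stop("restart_count must be >= 0", call. = FALSE)
  structure(
    list(
      subject_id = as.character(subject_id),
      session = as.integer(session),
      block = as.integer(block),
      trial_index = as.integer(trial_index),
      t = as.numeric(t),
      position = as.numeric(position),
      velocity = as.numeric(velocity),
      terminated_with_error = isTRUE(terminated_with_error),
      restart_count = as.integer(restart_count)
    ),
    class = "trial_trajectory"
  )
}

#' @export
print.trial_trajectory <- function(x, ...) {
  cat(sprintf(
    "<trial_trajectory> subject %s, session %d, block %d, trial %d: %d samples over %.3g s%s\n",
    x$subject_id, x$session, x$block, x$trial_index, length(x$t),
    if (length(x$t)) max(x$t) else 0,
    if (x$terminated_with_error) " [error-terminated]" else ""
  ))
  invisible(x)
}

# Spectral radius of the explicit-Euler update matrix I + dt * A for the
# closed-loop system xdot = v, vdot = -k_p x - k_d v. Radius > 1 means the
# discrete iteration diverges even though the continuous system is stable.
euler_spectral_radius <- function(k_p, k_d, dt) {
  disc <- k_d^2 - 4 * k_p
  if (disc < 0) {
    # complex pair: |1 + lambda dt|^2 = 1 - k_d dt + k_p dt^2
    sqrt(max(0, 1 - k_d * dt + k_p * dt^2))
  } else {
    r <- (-k_d + c(1, -1) * sqrt(disc)) / 2
    max(abs(1 + r * dt))
  }
}

#' Simulate one trial of the PD-controlled driving task
#'
#' Integrates the double-integrator car under the PD control law with
#' explicit Euler steps at the task frame rate: at each frame,
#' `a = k_p * (goal - x) - k_d * v + eps` with
#' `eps ~ Normal(0, noise_sd^2)` (motor noise on the commanded
#' acceleration), then `x <- x + v * dt` and `v <- v + a * dt`. The state
#' recorded at each frame is the state *before* that frame's update, so
#' the first sample is the starting condition.
#'
#' Velocity clipping at `±max_speed` is available but off by default:
#' saturated samples violate the linear PD model that the fitting stage
#' assumes, so synthetic cohorts are generated in ranges where the cap
#' never engages.
#'
#' @param params A [pd_params()] object.
#' @param config A [task_config()] object.
#' @param x0,v0 Starting position and velocity (defaults: at rest at the
#'   start line).
#' @param noise_sd Standard deviation of the additive acceleration noise
#'   (track units/s^2); 0 gives a deterministic trajectory.
#' @param seed Optional integer seed applied locally so the trajectory is
#'   reproducible without disturbing the caller's RNG stream.
#' @param clip_velocity If `TRUE`, velocity is clipped to
#'   `±config$max_speed` after each update.
#' @param sample_rate_override Optional finer sample rate (Hz) used for
#'   oracle convergence checks; the trial still covers
#'   `config$trial_duration` seconds.
#' @param subject_id,session,block,trial_index Identifiers stored on the
#'   returned trajectory.
#' @return A [trial_trajectory()].
#' @examples
#' cfg <- task_config()
#' tr <- simulate_trial(pd_params(8, 5), cfg, noise_sd = 0)
#' max(tr$position) # slight overshoot: damping ratio < 1
#' @export
simulate_trial <- function(params, config, x0 = 0, v0 = 0,
                           noise_sd = 0, seed = NULL,
                           clip_velocity = FALSE,
                           sample_rate_override = NULL,
                           subject_id = "s1", session = 1L, block = 1L,
                           trial_index = 1L) {
  stopifnot(inherits(config, "task_config"))
  if (!is.finite(params$k_p) || !is.finite(params$k_d)) {
    stop("PD gains must be finite", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)

  rate <- if (is.null(sample_rate_override)) config$sample_rate else sample_rate_override
  dt <- 1 / rate
  n <- as.integer(round(config$trial_duration * rate))

  if (euler_spectral_radius(params$k_p, params$k_d, dt) > 1) {
    warning(sprintf(
      "Euler step dt = %.4g is unstable for k_p = %g, k_d = %g; trajectory will diverge",
      dt, params$k_p, params$k_d
    ), call. = FALSE)
  }

  eps <- numeric(n)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit({
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      }, add = TRUE)
      set.seed(seed)
    }
    eps <- stats::rnorm(n, 0, noise_sd)
  }

  goal <- config$goal
  x <- numeric(n)
  v <- numeric(n)
  xi <- x0
  vi <- v0
  for (i in seq_len(n)) {
    x[i] <- xi
    v[i] <- vi
    a <- params$k_p * (goal - xi) - params$k_d * vi + eps[i]
    xi <- xi + vi * dt
    vi <- vi + a * dt
    if (clip_velocity) {
      vi <- max(min(vi, config$max_speed), -config$max_speed)
    }
  }

  trial_trajectory(
    t = (seq_len(n) - 1) * dt, position = x, velocity = v,
    subject_id = subject_id, session = session, block = block,
    trial_index = trial_index
  )
}

#' Closed-form trajectory of the noiseless PD-controlled car
#'
#' Exact solution of the linear second-order system
#' `x'' = k_p (goal - x) - k_d x'` (no noise, no velocity cap), used as
#' the analytic oracle for the discrete simulator. Writing
#' `u = x - goal`, the system is a damped harmonic oscillator
#' `u'' + k_d u' + k_p u = 0`; the under-, critically- and over-damped
#' branches are selected by the sign of `k_d^2 - 4 k_p`.
#'
#' @param params A [pd_params()] object.
#' @param config A [task_config()] object (supplies the goal position).
#' @param x0,v0 Starting position and velocity.
#' @param t Time points at which to evaluate the solution.
#' @return A list with numeric vectors `position` and `velocity`, aligned
#'   with `t`.
#' @examples
#' cfg <- task_config()
#' cf <- closed_form_trajectory(pd_params(4, 4), cfg, x0 = 0, v0 = 0,
#'                              t = seq(0, 5, by = 0.1))
#' max(cf$position) <= cfg$goal + 1e-12 # critical damping: no overshoot
#' @export
closed_form_trajectory <- function(params, config, x0 = 0, v0 = 0, t) {
  stopifnot(inherits(config, "task_config"), is.numeric(t))
  k_p <- params$k_p
  k_d <- params$k_d
  if (!is.finite(k_p) || !is.finite(k_d) || k_p <= 0 || k_d < 0) {
    stop("closed form requires finite k_p > 0 and k_d >= 0", call. = FALSE)
  }
  goal <- config$goal
  u0 <- x0 - goal
  disc <- k_d^2 - 4 * k_p
  alpha <- k_d / 2

  if (abs(disc) < 1e-12) {
    # critically damped: u = (A + B t) exp(-alpha t)
    A <- u0
    B <- v0 + alpha * u0
    e <- exp(-alpha * t)
    u <- (A + B * t) * e
    du <- (B - alpha * A - alpha * B * t) * e
  } else if (disc < 0) {
    # underdamped: damped frequency sqrt(k_p - k_d^2/4)
    wd <- sqrt(-disc) / 2
    A <- u0
    B <- (v0 + alpha * u0) / wd
    e <- exp(-alpha * t)
    cw <- cos(wd * t)
    sw <- sin(wd * t)
    u <- e * (A * cw + B * sw)
    du <- e * ((B * wd - alpha * A) * cw - (A * wd + alpha * B) * sw)
  } else {
    # overdamped: two real decay rates
    s <- sqrt(disc)
    r1 <- (-k_d + s) / 2
    r2 <- (-k_d - s) / 2
    C1 <- (v0 - r2 * u0) / (r1 - r2)
    C2 <- u0 - C1
    u <- C1 * exp(r1 * t) + C2 * exp(r2 * t)
    du <- C1 * r1 * exp(r1 * t) + C2 * r2 * exp(r2 * t)
  }

  list(position = u + goal, velocity = du)
}
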