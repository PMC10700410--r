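#' Task geometry and timing configuration
#'
#' Describes the simulated driving task: the car starts at position 0 and
#' must stop at a stop sign placed `track_length` away, within
#' `trial_duration` seconds, sampled at `sample_rate` frames per second.
#' The default maximum speed is chosen so that a car travelling flat-out
#' covers the track in 0.75 s, the task's design constant.
#'
#' @param track_length Distance from the start position to the stop sign
#'   (dimensionless track units; default 1).
#' @param max_speed Speed cap in track units per second. The default,
#'   `track_length / 0.75`, makes the nominal max-speed traversal time
#'   0.75 seconds.
#' @param sample_rate Samples per second (Hz); default 60, the frame rate
#'   at which position and velocity are recorded.
#' @param trial_duration Trial length in seconds; default 10.
#' @param goal_tolerance Distance from the stop sign within which the car
#'   must end the trial for it to count as successful.
#' @param offscreen_limit Distance past the stop sign at which the car is
#'   considered driven off the screen and the trial is terminated.
#'
#' @return An object of class `task_config`: a named list of the validated
#'   fields plus `dt` (`1 / sample_rate`), `n_samples`
#'   (`round(trial_duration * sample_rate)`) and `goal` (the stop-sign
#'   position, equal to `track_length`).
#' @examples
#' cfg <- task_config()
#' cfg$track_length / cfg$max_speed # 0.75 s traversal at top speed
#' @export
task_config <- function(track_length = 1,
                        max_speed = track_length / 0.75,
                        sample_rate = 60,
                        trial_duration = 10,
                        goal_tolerance = 0.05 * track_length,
                        offscreen_limit = 0.5 * track_length) {
  stopifnot(
    is.numeric(track_length), length(track_length) == 1L, is.finite(track_length),
    is.numeric(max_speed), length(max_speed) == 1L, is.finite(max_speed),
    is.numeric(sample_rate), length(sample_rate) == 1L, is.finite(sample_rate),
    is.numeric(trial_duration), length(trial_duration) == 1L, is.finite(trial_duration)
  )
  if (track_length <= 0) stop("`track_length` must be > 0", call. = FALSE)
  if (max_speed <= 0) stop("`max_speed` must be > 0", call. = FALSE)
  if (sample_rate <= 0) stop("`sample_rate` must be > 0", call. = FALSE)
  if (trial_duration <= 0) stop("`trial_duration` must be > 0", call. = FALSE)
  if (goal_tolerance < 0) stop("`goal_tolerance` must be >= 0", call. = FALSE)
  if (offscreen_limit <= 0) stop("`offscreen_limit` must be > 0", call. = FALSE)

  structure(
    list(
      track_length = track_length,
      max_speed = max_speed,
      sample_rate = sample_rate,
      trial_duration = trial_duration,
      goal_tolerance = goal_tolerance,
      offscreen_limit = offscreen_limit,
      dt = 1 / sample_rate,
      n_samples = as.integer(round(trial_duration * sample_rate)),
      goal = track_length
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  track: 0 -> %g (goal), max speed %g/s (traversal %.3g s)\n",
              x$track_length, x$max_speed, x$track_length / x$max_speed))
  cat(sprintf("  sampling: %g Hz for %g s (%d samples), dt = %.5g s\n",
              x$sample_rate, x$trial_duration, x$n_samples, x$dt))
  cat(sprintf("  goal tolerance %g, offscreen limit %g\n",
              x$goal_tolerance, x$offscreen_limit))
  invisible(x)
}

#' Proportional-derivative controller gains
#'
#' The PD control law commands acceleration
#' `a = k_p * (goal - x) - k_d * v`: the drive gain `k_p` accelerates the
#' car toward the goal in proportion to the remaining distance, and the
#' damping gain `k_d` decelerates it in proportion to current velocity,
#' like friction. Both gains must be strictly positive: downstream
#' analyses work with their natural logarithms.
#'
#' @param k_p Drive gain (1/s^2); must be > 0 and finite.
#' @param k_d Damping gain (1/s); must be > 0 and finite.
#' @return An object of class `pd_params` with elements `k_p` and `k_d`.
#' @examples
#' p <- pd_params(k_p = 9, k_d = 3)
#' damping_ratio(p) # 0.5: underdamped, expect overshoot
#' @export
pd_params <- function(k_p, k_d) {
  stopifnot(is.numeric(k_p), length(k_p) == 1L, is.numeric(k_d), length(k_d) == 1L)
  if (!is.finite(k_p) || !is.finite(k_d)) {
    stop("PD gains must be finite", call. = FALSE)
  }
  if (k_p <= 0 || k_d <= 0) {
    stop("PD gains must be strictly positive (log transform requires k_p > 0, k_d > 0)",
         call. = FALSE)
  }
  structure(list(k_p = k_p, k_d = k_d), class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf("<pd_params> k_p = %g, k_d = %g (damping ratio %.3g)\n",
              x$k_p, x$k_d, damping_ratio(x)))
  invisible(x)
}

#' Damping ratio of a PD-controlled car
#'
#' Computes `k_d / (2 * sqrt(k_p))`, the damping ratio of the closed-loop
#' second-order system. Values below 1 predict overshoot of the stop
#' sign; values of 1 or more preclude overshoot in the noiseless system.
#'
#' @param params A [pd_params()] object (or list with `k_p`, `k_d`).
#' @return The dimensionless damping ratio.
#' @examples
#' damping_ratio(pd_params(4, 4)) # 1: critically damped
#' @export
damping_ratio <- function(params) {
  if (!is.numeric(params$k_p) || params$k_p <= 0) {
    stop("damping ratio requires k_p > 0", call. = FALSE)
  }
  if (params$k_d < 0) stop("damping ratio requires k_d >= 0", call. = FALSE)
  params$k_d / (2 * sqrt(params$k_p))
}
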