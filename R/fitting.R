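#' Per-sample acceleration from recorded velocity
#'
#' Acceleration is not recorded by the task; it is derived by forward
#' finite differences of the recorded velocity:
#' `a_i = (v[i+1] - v[i]) / (t[i+1] - t[i])`, aligned to the *left*
#' endpoint, i.e. to the first `n - 1` time stamps. This alignment is the
#' exact inverse of the explicit-Euler update used by the simulator, so a
#' noiseless simulated trial is recovered exactly by the regression.
#' Differencing velocity (rather than twice-differencing position)
#' amplifies measurement noise only once.
#'
#' @param traj A [trial_trajectory()] with at least 3 samples.
#' @return A list with `t` (the first `n - 1` time stamps),
#'   `acceleration` (length `n - 1`) and `index` (the sample indices the
#'   series is aligned to).
#' @examples
#' tr <- simulate_trial(pd_params(4, 4), task_config())
#' acc <- estimate_derivatives(tr)
#' length(acc$acceleration) == length(tr$t) - 1
#' @export
estimate_derivatives <- function(traj) {
  stopifnot(inherits(traj, "trial_trajectory"))
  n <- length(traj$t)
  if (n < 3) stop("need at least 3 samples to estimate acceleration", call. = FALSE)
  dts <- diff(traj$t)
  if (any(dts <= 0)) stop("duplicate or non-increasing time stamps", call. = FALSE)
  idx <- seq_len(n - 1)
  list(
    t = traj$t[idx],
    acceleration = diff(traj$velocity) / dts,
    index = idx
  )
}

pd_fit_invalid <- function(reason, traj = NULL) {
  structure(
    list(
      subject_id = if (is.null(traj)) NA_character_ else traj$subject_id,
      session = if (is.null(traj)) NA_integer_ else traj$session,
      block = if (is.null(traj)) NA_integer_ else traj$block,
      trial_index = if (is.null(traj)) NA_integer_ else traj$trial_index,
      k_p = NA_real_, k_d = NA_real_,
      log_k_p = NA_real_, log_k_d = NA_real_,
      r_squared_sim = NA_real_, n_samples_used = 0L,
      valid = FALSE, reason = reason
    ),
    class = "pd_fit"
  )
}

#' @export
print.pd_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "<pd_fit> k_p = %.4g, k_d = %.4g (log %.3g / %.3g), R2_sim = %s, n = %d\n",
      x$k_p, x$k_d, x$log_k_p, x$log_k_d,
      if (is.na(x$r_squared_sim)) "not assessed" else sprintf("%.3f", x$r_squared_sim),
      x$n_samples_used
    ))
  } else {
    cat(sprintf("<pd_fit> invalid (%s)\n", x$reason))
  }
  invisible(x)
}

#' Fit PD gains to one trial by zero-intercept least squares
#'
#' Regresses the finite-difference acceleration on the goal error
#' `e_t = goal - x_t` and its derivative `-v_t`, with no intercept. The
#' coefficient on the error is the drive gain `k_p`; the coefficient on
#' the error derivative is the damping gain `k_d`. Fits with a
#' non-positive coefficient or a rank-deficient design are marked invalid
#' with a reason code rather than raising an error, so cohort-level
#' pipelines keep running.
#'
#' By default the full recorded trace is fitted. With
#' `truncate_post_stop = TRUE`, samples after the car has settled at the
#' sign (within `config$goal_tolerance` of the goal with speed below
#' `stop_speed_frac * max_speed` for the rest of the trial) are dropped.
#'
#' @param traj A [trial_trajectory()].
#' @param config A [task_config()] (supplies the goal position).
#' @param assess If `TRUE` (default), also run [assess_fit()] and store
#'   the simulation R-squared on the result.
#' @param truncate_post_stop Drop samples after the car has settled at
#'   the stop sign? Default `FALSE` (fit the full trace).
#' @param stop_speed_frac Speed threshold for "settled", as a fraction of
#'   `max_speed`; only used when `truncate_post_stop = TRUE`.
#' @return A `pd_fit` object: `k_p`, `k_d`, their natural logs,
#'   `r_squared_sim`, `n_samples_used`, `valid` and `reason`.
#' @examples
#' cfg <- task_config()
#' tr <- simulate_trial(pd_params(4, 4), cfg)
#' fit_trial_pd(tr, cfg) # recovers k_p = k_d = 4 exactly (noiseless)
#' @export
fit_trial_pd <- function(traj, config, assess = TRUE,
                         truncate_post_stop = FALSE, stop_speed_frac = 0.02) {
  stopifnot(inherits(traj, "trial_trajectory"), inherits(config, "task_config"))
  n <- length(traj$t)
  if (n < 3) return(pd_fit_invalid("too_few_samples", traj))
  if (any(diff(traj$t) <= 0)) return(pd_fit_invalid("nonmonotone_time", traj))

  keep <- seq_len(n)
  if (truncate_post_stop) {
    settled <- abs(config$goal - traj$position) <= config$goal_tolerance &
      abs(traj$velocity) <= stop_speed_frac * config$max_speed
    # first index after which every later sample is settled
    still_moving <- rev(cumsum(rev(!settled)) > 0)
    last_active <- if (any(still_moving)) max(which(still_moving)) else 1L
    keep <- seq_len(min(n, last_active + 1L))
    if (length(keep) < 3) keep <- seq_len(min(n, 3L))
  }

  tt <- traj$t[keep]
  xx <- traj$position[keep]
  vv <- traj$velocity[keep]

  a <- diff(vv) / diff(tt)
  m <- length(a)
  err <- config$goal - xx[seq_len(m)]
  errdot <- -vv[seq_len(m)]

  if (all(abs(err) < 1e-12) && all(abs(errdot) < 1e-12)) {
    return(pd_fit_invalid("degenerate", traj))
  }

  X <- cbind(err = err, errdot = errdot)
  qrX <- qr(X)
  if (qrX$rank < 2) return(pd_fit_invalid("rank_deficient", traj))
  beta <- qr.coef(qrX, a)

  if (!all(is.finite(beta))) return(pd_fit_invalid("nonfinite_fit", traj))
  if (beta[["err"]] <= 0) return(pd_fit_invalid("nonpositive_k_p", traj))
  if (beta[["errdot"]] <= 0) return(pd_fit_invalid("nonpositive_k_d", traj))

  fit <- structure(
    list(
      subject_id = traj$subject_id, session = traj$session,
      block = traj$block, trial_index = traj$trial_index,
      k_p = unname(beta[["err"]]), k_d = unname(beta[["errdot"]]),
      log_k_p = log(unname(beta[["err"]])),
      log_k_d = log(unname(beta[["errdot"]])),
      r_squared_sim = NA_real_, n_samples_used = m,
      valid = TRUE, reason = "ok"
    ),
    class = "pd_fit"
  )
  if (assess) fit$r_squared_sim <- assess_fit(traj, fit, config)
  fit
}

# Euler path at arbitrary (possibly non-uniform) time stamps; noiseless.
euler_path <- function(k_p, k_d, goal, x0, v0, t) {
  n <- length(t)
  x <- numeric(n)
  v <- numeric(n)
  xi <- x0
  vi <- v0
  for (i in seq_len(n)) {
    x[i] <- xi
    v[i] <- vi
    if (i < n) {
      dt <- t[i + 1] - t[i]
      a <- k_p * (goal - xi) - k_d * vi
      xi <- xi + vi * dt
      vi <- vi + a * dt
    }
  }
  list(position = x, velocity = v)
}

#' Goodness of fit by forward simulation
#'
#' Re-simulates the trial from its recorded starting position and
#' velocity using the fitted gains (noiseless), then computes the
#' R-squared between predicted and observed velocity across all frames:
#' `R2 = 1 - SS_res / SS_tot`, with `SS_tot` taken about the mean
#' observed velocity. Values can be negative when the simulation predicts
#' velocity worse than its mean.
#'
#' @param traj The observed [trial_trajectory()].
#' @param fit A valid `pd_fit` for that trial.
#' @param config A [task_config()].
#' @return The simulation R-squared (numeric scalar).
#' @export
assess_fit <- function(traj, fit, config) {
  stopifnot(inherits(traj, "trial_trajectory"), inherits(config, "task_config"))
  if (!isTRUE(fit$valid)) stop("cannot assess an invalid fit", call. = FALSE)
  pred <- euler_path(fit$k_p, fit$k_d, config$goal,
                     traj$position[1], traj$velocity[1], traj$t)
  obs <- traj$velocity
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred$velocity)^2) / ss_tot
}

#' Fit every trial in a collection
#'
#' Applies [fit_trial_pd()] to each trajectory and returns a tidy
#' per-trial parameter table. Trials flagged as error-terminated are not
#' fitted (their gains would reflect a truncated, restarted attempt);
#' they appear in the table with `valid = FALSE` and reason
#' `"error_trial"` and still contribute to the error-count behavioral
#' index downstream.
#'
#' @param trajs A list of [trial_trajectory()] objects, or a long
#'   trajectory tibble as produced by [trajectories_to_tibble()] /
#'   [read_trajectories()].
#' @param config A [task_config()].
#' @inheritParams fit_trial_pd
#' @return A tibble with one row per trial: identifiers, `k_p`, `k_d`,
#'   `log_k_p`, `log_k_d`, `r_squared_sim`, `n_samples_used`, `valid`,
#'   `reason`, `final_position`, `terminated_with_error`.
#' @export
fit_trajectories <- function(trajs, config, assess = TRUE,
                             truncate_post_stop = FALSE) {
  if (is.data.frame(trajs)) trajs <- tibble_to_trajectories(trajs)
  stopifnot(is.list(trajs))
  rows <- lapply(trajs, function(tr) {
    if (tr$terminated_with_error) {
      f <- pd_fit_invalid("error_trial", tr)
    } else {
      f <- fit_trial_pd(tr, config, assess = assess,
                        truncate_post_stop = truncate_post_stop)
    }
    tibble::tibble(
      subject_id = tr$subject_id, session = tr$session, block = tr$block,
      trial = tr$trial_index,
      k_p = f$k_p, k_d = f$k_d, log_k_p = f$log_k_p, log_k_d = f$log_k_d,
      r_squared_sim = f$r_squared_sim, n_samples_used = f$n_samples_used,
      valid = f$valid, reason = f$reason,
      final_position = traj_final_position(tr),
      terminated_with_error = tr$terminated_with_error
    )
  })
  dplyr::bind_rows(rows)
}

traj_final_position <- function(tr) {
  if (length(tr$position)) tr$position[length(tr$position)] else NA_real_
}

#' Per-subject, per-session parameter and behavior summaries
#'
#' Averages log gains over *valid* trials within each subject-session
#' cell and computes the behavioral indices: mean final car position
#' (over valid trials) and the count of error-terminated trials with its
#' log. The log uses `log(count + 1)` so subjects with zero error trials
#' are defined. Cells with zero valid trials are kept, flagged with
#' `missing = TRUE` and `NA` parameter means.
#'
#' @param fits A per-trial parameter table from [fit_trajectories()].
#' @return A tibble with one row per subject x session:
#'   `mean_log_k_p`, `mean_log_k_d`, `n_valid_trials`,
#'   `final_position_mean`, `error_trial_count`, `log_error_trial_count`,
#'   `mean_r_squared_sim`, `missing`.
#' @export
summarize_sessions <- function(fits) {
  stopifnot(is.data.frame(fits))
  fits |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(
      mean_log_k_p = mean(.data$log_k_p[.data$valid]),
      mean_log_k_d = mean(.data$log_k_d[.data$valid]),
      n_valid_trials = sum(.data$valid),
      final_position_mean = mean(.data$final_position[.data$valid]),
      error_trial_count = sum(.data$terminated_with_error),
      mean_r_squared_sim = mean(.data$r_squared_sim[.data$valid]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      log_error_trial_count = log(.data$error_trial_count + 1),
      missing = .data$n_valid_trials == 0L,
      mean_log_k_p = ifelse(.data$missing, NA_real_, .data$mean_log_k_p),
      mean_log_k_d = ifelse(.data$missing, NA_real_, .data$mean_log_k_d),
      final_position_mean = ifelse(.data$missing, NA_real_, .data$final_position_mean)
    )
}

#' Half-session parameter summaries for split-half reliability
#'
#' Assigns each valid trial of a session to one of two halves under the
#' given [split_scheme()] and averages log gains within each half.
#'
#' @param fits A per-trial parameter table from [fit_trajectories()].
#' @param scheme A [split_scheme()].
#' @return A tibble with one row per subject x session x half
#'   (`half` in 1:2): `mean_log_k_p`, `mean_log_k_d`, `n_trials`.
#' @export
summarize_halves <- function(fits, scheme = split_scheme("odd_even")) {
  stopifnot(is.data.frame(fits), inherits(scheme, "split_scheme"))
  fits |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::mutate(half = scheme$assign(.data$trial)) |>
    dplyr::group_by(.data$subject_id, .data$session, .data$half) |>
    dplyr::summarise(
      mean_log_k_p = mean(.data$log_k_p),
      mean_log_k_d = mean(.data$log_k_d),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}
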