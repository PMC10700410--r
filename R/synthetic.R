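#' Specification of a synthetic cohort
#'
#' Collects every knob of the synthetic-data generator: the subject-level
#' distribution of the log gains (log-normal gains, matching the
#' right-skew of fitted K_p/K_d across people), their between-parameter
#' and across-session correlations, trial-level motor noise, planted
#' standardized fear effects, covariate distributions, the error-trial
#' rate and the session length. Defaults describe a plausible mobile
#' cohort: about a hundred subjects, two sessions of two 10-trial
#' blocks, gains centred near K_p = 8 and K_d = 5 (damping ratio ~0.9,
#' mild overshoot), high across-session stability and a moderate
#' negative fear effect on both log gains.
#'
#' @param n_subjects Number of subjects.
#' @param mean_log_k_p,sd_log_k_p Mean and between-subject SD of log K_p.
#' @param mean_log_k_d,sd_log_k_d Mean and between-subject SD of log K_d.
#' @param param_correlation Residual correlation between a subject's log
#'   K_p and log K_d (after the fear effect).
#' @param session_correlation Correlation of a subject's true log gains
#'   across the two sessions (test-retest stability of the trait).
#' @param noise_sd Within-trial motor noise SD on acceleration
#'   (track units/s^2).
#' @param trial_sd_log_k_p,trial_sd_log_k_d Trial-to-trial SD of a
#'   subject's log gains about their session mean: people do not reuse
#'   identical control gains on every trial.
#' @param fear_effect_log_k_p,fear_effect_log_k_d Planted standardized
#'   effects of fear on the log gains (negative: more fearful subjects
#'   drive with lower gains).
#' @param fear_mean,fear_sd,fear_range PANAS-X fear-scale score
#'   distribution (truncated normal; the default range 6-30 is a 6-item,
#'   1-5 scale).
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param p_male,p_bachelor,p_mobile,p_same_day Bernoulli rates for the
#'   binary covariates.
#' @param error_rate Probability that a trial ends in an error
#'   (terminated early, excluded from fitting).
#' @param trials_per_session Trials per session (two blocks of 10 by
#'   default).
#' @param n_blocks Blocks per session.
#' @param seed Integer seed; every draw in the generator flows from it.
#' @return A `cohort_spec` object (validated named list).
#' @export
cohort_spec <- function(n_subjects = 100,
                        mean_log_k_p = log(8), sd_log_k_p = 0.5,
                        mean_log_k_d = log(5), sd_log_k_d = 0.5,
                        param_correlation = 0.3,
                        session_correlation = 0.85,
                        noise_sd = 3.5,
                        trial_sd_log_k_p = 0.35, trial_sd_log_k_d = 0.35,
                        fear_effect_log_k_p = -0.29,
                        fear_effect_log_k_d = -0.29,
                        fear_mean = 10.5, fear_sd = 3.5, fear_range = c(6, 30),
                        age_mean = 35.8, age_sd = 9.5, age_range = c(18, 80),
                        p_male = 0.64, p_bachelor = 0.79,
                        p_mobile = 0.9, p_same_day = 0.1,
                        error_rate = 0.05,
                        trials_per_session = 20, n_blocks = 2,
                        seed = 1L) {
  stopifnot(
    n_subjects >= 1,
    sd_log_k_p >= 0, sd_log_k_d >= 0, noise_sd >= 0,
    trial_sd_log_k_p >= 0, trial_sd_log_k_d >= 0,
    abs(param_correlation) <= 1, abs(session_correlation) <= 1,
    is.finite(fear_effect_log_k_p), is.finite(fear_effect_log_k_d),
    error_rate >= 0, error_rate <= 1,
    p_male >= 0, p_male <= 1, p_bachelor >= 0, p_bachelor <= 1,
    p_mobile >= 0, p_mobile <= 1, p_same_day >= 0, p_same_day <= 1,
    trials_per_session >= 1, n_blocks >= 1
  )
  for (b in list(fear_effect_log_k_p, fear_effect_log_k_d)) {
    if (abs(b) > 1) stop("standardized fear effects must be in [-1, 1]", call. = FALSE)
  }
  structure(mget(names(formals())), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d subjects, 2 sessions x %d trials; log K_p ~ N(%.2f, %.2f), log K_d ~ N(%.2f, %.2f)\n",
    x$n_subjects, x$trials_per_session, x$mean_log_k_p, x$sd_log_k_p,
    x$mean_log_k_d, x$sd_log_k_d
  ))
  cat(sprintf(
    "  session corr %.2f, param corr %.2f, noise sd %.2g, fear effects (%.2f, %.2f), error rate %.2g, seed %s\n",
    x$session_correlation, x$param_correlation, x$noise_sd,
    x$fear_effect_log_k_p, x$fear_effect_log_k_d, x$error_rate, format(x$seed)
  ))
  invisible(x)
}

# Deterministic sub-seed for a named random substream, below 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Draw a synthetic cohort of subjects with known true parameters
#'
#' Samples per-subject covariates and true log gains for both sessions.
#' The construction plants exact target structure: writing `z_f` for the
#' sample-standardized fear score and `beta_j` for the planted effect on
#' log parameter `j`, each session's standardized true parameter is
#' `beta_j * z_f + sqrt(1 - beta_j^2) * eta`, where the residuals `eta`
#' share a common subject component sized so that the *total*
#' across-session correlation of the true parameter equals
#' `session_correlation`, and within-session residuals for K_p and K_d
#' are correlated at `param_correlation`. This requires
#' `session_correlation >= beta_j^2`; otherwise the implied covariance
#' is impossible and an error is raised.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, covariates
#'   (`fear`, `age`, `gender_male`, `education_bachelor_plus`,
#'   `device_mobile`, `same_day_sessions`) and true parameters
#'   `true_log_k_p_s1`, `true_log_k_d_s1`, `true_log_k_p_s2`,
#'   `true_log_k_d_s2`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  set.seed(substream_seed(spec$seed, "cohort"))

  fear <- rtruncnorm1(n, spec$fear_mean, spec$fear_sd,
                      spec$fear_range[1], spec$fear_range[2])
  age <- rtruncnorm1(n, spec$age_mean, spec$age_sd,
                     spec$age_range[1], spec$age_range[2])
  gender_male <- stats::rbinom(n, 1, spec$p_male)
  education_bachelor_plus <- stats::rbinom(n, 1, spec$p_bachelor)
  device_mobile <- stats::rbinom(n, 1, spec$p_mobile)
  same_day_sessions <- stats::rbinom(n, 1, spec$p_same_day)

  z_f <- if (n > 1 && stats::sd(fear) > 0) as.numeric(scale(fear)) else numeric(n)

  beta <- c(p = spec$fear_effect_log_k_p, d = spec$fear_effect_log_k_d)
  rho_s <- spec$session_correlation
  rho_pd <- spec$param_correlation

  # residual across-session correlation needed so that the total
  # across-session correlation of the standardized parameter is rho_s
  rho_eta <- vapply(beta, function(b) {
    if (1 - b^2 < 1e-12) return(0)
    r <- (rho_s - b^2) / (1 - b^2)
    if (r < 0 || r > 1) {
      stop("session_correlation incompatible with planted fear effect ",
           "(implied residual correlation outside [0, 1])", call. = FALSE)
    }
    r
  }, numeric(1))

  # shared subject component g (corr rho_pd across parameters) plus
  # session-specific residuals (corr rho_pd within a session)
  corr2 <- function(nn, rho) {
    z1 <- stats::rnorm(nn)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(nn)
    cbind(z1, z2)
  }
  g <- corr2(n, rho_pd)
  e1 <- corr2(n, rho_pd)
  e2 <- corr2(n, rho_pd)

  std_param <- function(j, session_eps) {
    b <- beta[[j]]
    col <- if (j == "p") 1 else 2
    eta <- sqrt(rho_eta[[j]]) * g[, col] +
      sqrt(1 - rho_eta[[j]]) * session_eps[, col]
    b * z_f + sqrt(1 - b^2) * eta
  }

  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    fear = fear, age = age,
    gender_male = gender_male,
    education_bachelor_plus = education_bachelor_plus,
    device_mobile = device_mobile,
    same_day_sessions = same_day_sessions,
    true_log_k_p_s1 = spec$mean_log_k_p + spec$sd_log_k_p * std_param("p", e1),
    true_log_k_d_s1 = spec$mean_log_k_d + spec$sd_log_k_d * std_param("d", e1),
    true_log_k_p_s2 = spec$mean_log_k_p + spec$sd_log_k_p * std_param("p", e2),
    true_log_k_d_s2 = spec$mean_log_k_d + spec$sd_log_k_d * std_param("d", e2)
  )
}

#' Simulate the full trial set for a sampled cohort
#'
#' For every subject x session x trial, simulates the driving trial with
#' that subject-session's true gains (jittered per trial by the spec's
#' trial-to-trial SDs) and the spec's motor noise, using a
#' vectorized Euler stepper (all trials advance together, one frame at a
#' time). Error trials are injected at `spec$error_rate`: they are
#' truncated at a uniformly drawn frame (at least half a second in) and
#' flagged `terminated_with_error`; only their count feeds the analysis.
#'
#' @param cohort A cohort table from [sample_cohort()].
#' @param config A [task_config()].
#' @param spec The [cohort_spec()] the cohort was drawn from.
#' @return A long trajectory tibble in the standard layout: `subject_id`,
#'   `session`, `block`, `trial`, `t`, `position`, `velocity`,
#'   `terminated_with_error`, `restart_count`; one row per frame.
#' @export
generate_cohort_trajectories <- function(cohort, config, spec) {
  stopifnot(is.data.frame(cohort), inherits(config, "task_config"),
            inherits(spec, "cohort_spec"))
  n_tr <- spec$trials_per_session
  trials_per_block <- ceiling(n_tr / spec$n_blocks)

  grid <- tidyr::expand_grid(
    subject_id = cohort$subject_id,
    session = c(1L, 2L),
    trial = seq_len(n_tr)
  ) |>
    dplyr::mutate(block = as.integer((.data$trial - 1) %/% trials_per_block + 1L))

  par_lookup <- function(sess, par) {
    col <- sprintf("true_log_k_%s_s%d", par, sess)
    cohort[[col]][match(grid$subject_id, cohort$subject_id)]
  }
  log_kp <- ifelse(grid$session == 1L, par_lookup(1L, "p"), par_lookup(2L, "p"))
  log_kd <- ifelse(grid$session == 1L, par_lookup(1L, "d"), par_lookup(2L, "d"))

  m <- nrow(grid)
  set.seed(substream_seed(spec$seed, "trial-params"))
  log_kp <- log_kp + stats::rnorm(m, 0, spec$trial_sd_log_k_p)
  log_kd <- log_kd + stats::rnorm(m, 0, spec$trial_sd_log_k_d)
  kp <- exp(log_kp)
  kd <- exp(log_kd)
  n_frames <- config$n_samples
  dt <- config$dt

  set.seed(substream_seed(spec$seed, "error-trials"))
  is_error <- stats::runif(m) < spec$error_rate
  min_frames <- max(3L, as.integer(round(0.5 * config$sample_rate)))
  cut_frame <- ifelse(
    is_error,
    min_frames + floor(stats::runif(m) * (n_frames - min_frames)),
    n_frames
  )
  restart_count <- stats::rpois(m, spec$error_rate)

  set.seed(substream_seed(spec$seed, "noise"))
  X <- matrix(0, n_frames, m)
  V <- matrix(0, n_frames, m)
  x <- numeric(m)
  v <- numeric(m)
  goal <- config$goal
  for (i in seq_len(n_frames)) {
    X[i, ] <- x
    V[i, ] <- v
    eps <- if (spec$noise_sd > 0) stats::rnorm(m, 0, spec$noise_sd) else 0
    a <- kp * (goal - x) - kd * v + eps
    x <- x + v * dt
    v <- v + a * dt
  }

  keep_len <- as.integer(cut_frame)
  idx_trial <- rep.int(seq_len(m), keep_len)
  frame <- sequence(keep_len)

  tibble::tibble(
    subject_id = grid$subject_id[idx_trial],
    session = grid$session[idx_trial],
    block = grid$block[idx_trial],
    trial = grid$trial[idx_trial],
    t = (frame - 1) * dt,
    position = X[cbind(frame, idx_trial)],
    velocity = V[cbind(frame, idx_trial)],
    terminated_with_error = is_error[idx_trial],
    restart_count = restart_count[idx_trial]
  )
}

#' One-call synthetic dataset: cohort, covariates and trajectories
#'
#' Convenience wrapper used by the pipeline and examples: draws the
#' cohort and simulates all trajectories.
#'
#' @inheritParams generate_cohort_trajectories
#' @param config A [task_config()].
#' @return A list with `cohort` (subject table with true parameters and
#'   covariates) and `trajectories` (long trajectory tibble).
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = task_config()) {
  cohort <- sample_cohort(spec)
  trajectories <- generate_cohort_trajectories(cohort, config, spec)
  list(cohort = cohort, trajectories = trajectories)
}
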