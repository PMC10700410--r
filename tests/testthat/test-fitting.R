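cfg <- task_config()

test_that("finite-difference acceleration is exact on polynomial motion", {
  # constant position, zero velocity
  tr <- trial_trajectory(t = seq(0, 1, by = 1 / 60),
                         position = rep(0.5, 61), velocity = rep(0, 61))
  acc <- estimate_derivatives(tr)
  expect_equal(acc$acceleration, rep(0, 60))
  expect_equal(length(acc$t), 60)
  expect_equal(acc$t, tr$t[1:60])

  # linear position, constant velocity
  t <- seq(0, 1, by = 1 / 60)
  tr <- trial_trajectory(t = t, position = 0.3 * t, velocity = rep(0.3, 61))
  expect_equal(estimate_derivatives(tr)$acceleration, rep(0, 60))

  # v(t) = 3t: acceleration exactly 3 at every aligned sample
  tr <- trial_trajectory(t = t, position = 1.5 * t^2, velocity = 3 * t)
  expect_equal(estimate_derivatives(tr)$acceleration, rep(3, 60),
               tolerance = 1e-9)
})

test_that("derivative estimation rejects degenerate time bases", {
  tr <- trial_trajectory(t = c(0, 1), position = c(0, 1), velocity = c(1, 1))
  expect_error(estimate_derivatives(tr), "at least 3")
})

test_that("noiseless fits recover generating gains across the damping grid", {
  grid <- pd_grid()
  for (i in seq_len(nrow(grid))) {
    p <- pd_params(grid$k_p[i], grid$k_d[i])
    # task frame rate: relative error under 1%
    tr60 <- simulate_trial(p, cfg, noise_sd = 0)
    f60 <- fit_trial_pd(tr60, cfg, assess = FALSE)
    expect_true(f60$valid)
    expect_lt(abs(f60$k_p - p$k_p) / p$k_p, 0.01)
    expect_lt(abs(f60$k_d - p$k_d) / p$k_d, 0.01)
    # fine sampling: under 0.1%
    tr600 <- simulate_trial(p, cfg, noise_sd = 0, sample_rate_override = 600)
    f600 <- fit_trial_pd(tr600, cfg, assess = FALSE)
    expect_lt(abs(f600$k_p - p$k_p) / p$k_p, 0.001)
    expect_lt(abs(f600$k_d - p$k_d) / p$k_d, 0.001)
  }
})

test_that("fit coefficients equal the zero-intercept normal-equation solution", {
  trials <- list(
    handmade_trial(),
    simulate_trial(pd_params(8, 5), cfg, noise_sd = 2, seed = 3),
    simulate_trial(pd_params(3, 1.5), cfg, noise_sd = 1, seed = 4)
  )
  for (tr in trials) {
    f <- fit_trial_pd(tr, cfg, assess = FALSE)
    n <- length(tr$t)
    a <- diff(tr$velocity) / diff(tr$t)
    X <- cbind(cfg$goal - tr$position[-n], -tr$velocity[-n])
    beta <- solve(t(X) %*% X, t(X) %*% a)
    if (f$valid) {
      expect_equal(c(f$k_p, f$k_d), as.numeric(beta), tolerance = 1e-10)
    } else {
      expect_true(any(beta <= 0))
    }
  }
})

test_that("degenerate and ill-posed trials yield flagged invalid fits", {
  t <- seq(0, 2, by = 1 / 60)
  at_goal <- trial_trajectory(t = t, position = rep(cfg$goal, length(t)),
                              velocity = rep(0, length(t)))
  f <- fit_trial_pd(at_goal, cfg)
  expect_false(f$valid)
  expect_equal(f$reason, "degenerate")

  # motion inconsistent with positive gains: decelerating away from the goal
  weird <- trial_trajectory(t = 0:3, position = c(0, 0, -1, -3),
                            velocity = c(0, -1, -2, -3))
  f2 <- fit_trial_pd(weird, cfg)
  expect_false(f2$valid)
  expect_match(f2$reason, "nonpositive")
})

test_that("fitting at moderate noise is unbiased over many replicates", {
  p <- pd_params(8, 5)
  n_rep <- 200
  kp_hat <- numeric(n_rep)
  kd_hat <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    tr <- simulate_trial(p, cfg, noise_sd = 1, seed = 5000 + r)
    f <- fit_trial_pd(tr, cfg, assess = FALSE)
    kp_hat[r] <- f$k_p
    kd_hat[r] <- f$k_d
  }
  expect_lt(abs(mean(kp_hat) - p$k_p), 3 * sd(kp_hat) / sqrt(n_rep))
  expect_lt(abs(mean(kd_hat) - p$k_d), 3 * sd(kd_hat) / sqrt(n_rep))
})

test_that("closed-loop least squares keeps its finite-sample bias small at cohort noise", {
  # lagged-state regressors make plain LS consistent but not exactly
  # unbiased; at the generator default noise the relative bias stays small
  p <- pd_params(8, 5)
  est <- vapply(seq_len(300), function(r) {
    f <- fit_trial_pd(simulate_trial(p, cfg, noise_sd = 3.5, seed = 7000 + r),
                      cfg, assess = FALSE)
    c(f$k_p, f$k_d)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - p$k_p) / p$k_p, 0.05)
  expect_lt(abs(mean(est[2, ]) - p$k_d) / p$k_d, 0.05)
})

test_that("simulation R-squared is 1 for self-generated data and matches the variance ratio under noise", {
  p <- pd_params(8, 5)
  clean <- simulate_trial(p, cfg, noise_sd = 0)
  f <- fit_trial_pd(clean, cfg)
  expect_gt(f$r_squared_sim, 1 - 1e-9)
  expect_lte(f$r_squared_sim, 1)

  noisy <- simulate_trial(p, cfg, noise_sd = 4, seed = 11)
  fn <- fit_trial_pd(noisy, cfg)
  sim <- simulate_trial(pd_params(fn$k_p, fn$k_d), cfg,
                        x0 = noisy$position[1], v0 = noisy$velocity[1],
                        noise_sd = 0)
  r2_direct <- 1 - sum((noisy$velocity - sim$velocity)^2) /
    sum((noisy$velocity - mean(noisy$velocity))^2)
  expect_equal(fn$r_squared_sim, r2_direct, tolerance = 1e-12)
  expect_lt(fn$r_squared_sim, 1)
})

test_that("assess_fit refuses invalid fits", {
  tr <- simulate_trial(pd_params(4, 4), cfg)
  bad <- pdrive:::pd_fit_invalid("degenerate", tr)
  expect_error(assess_fit(tr, bad, cfg), "invalid")
})

test_that("session summaries average valid trials and flag empty cells", {
  fits <- tibble::tibble(
    subject_id = "A", session = 1L, block = 1L, trial = 1:3,
    k_p = exp(c(1, 3, NA)), k_d = exp(c(0.5, 1.5, NA)),
    log_k_p = c(1, 3, NA), log_k_d = c(0.5, 1.5, NA),
    r_squared_sim = c(0.9, 0.8, NA), n_samples_used = c(599L, 599L, 0L),
    valid = c(TRUE, TRUE, FALSE), reason = c("ok", "ok", "error_trial"),
    final_position = c(1.0, 1.1, 0.4),
    terminated_with_error = c(FALSE, FALSE, TRUE)
  )
  s <- summarize_sessions(fits)
  expect_equal(s$mean_log_k_p, 2)
  expect_equal(s$mean_log_k_d, 1)
  expect_equal(s$n_valid_trials, 2L)
  expect_equal(s$final_position_mean, 1.05)
  expect_equal(s$error_trial_count, 1L)
  expect_equal(s$log_error_trial_count, log(2))
  expect_false(s$missing)

  all_bad <- dplyr::mutate(fits, valid = FALSE)
  s2 <- summarize_sessions(all_bad)
  expect_true(s2$missing)
  expect_true(is.na(s2$mean_log_k_p))
})

test_that("session mean log gains recover a subject's generating value", {
  p <- pd_params(8, 5)
  trials <- lapply(1:20, function(i) {
    simulate_trial(p, cfg, noise_sd = 2, seed = 900 + i,
                   subject_id = "A", trial_index = i)
  })
  fits <- fit_trajectories(trials, cfg, assess = FALSE)
  s <- summarize_sessions(fits)
  se <- sd(fits$log_k_p) / sqrt(sum(fits$valid))
  expect_lt(abs(s$mean_log_k_p - log(p$k_p)), 3 * se)
})

test_that("error-terminated trials are excluded from fitting but counted", {
  p <- pd_params(8, 5)
  good <- simulate_trial(p, cfg, noise_sd = 1, seed = 1, trial_index = 1)
  bad <- simulate_trial(p, cfg, noise_sd = 1, seed = 2, trial_index = 2)
  bad$terminated_with_error <- TRUE
  fits <- fit_trajectories(list(good, bad), cfg, assess = FALSE)
  expect_equal(fits$reason, c("ok", "error_trial"))
  expect_equal(sum(fits$valid), 1L)
  s <- summarize_sessions(fits)
  expect_equal(s$error_trial_count, 1L)
})

test_that("post-stop truncation drops settled tail samples", {
  p <- pd_params(16, 8) # critically damped, settles quickly
  tr <- simulate_trial(p, cfg, noise_sd = 0)
  f_full <- fit_trial_pd(tr, cfg, assess = FALSE)
  f_trunc <- fit_trial_pd(tr, cfg, assess = FALSE, truncate_post_stop = TRUE)
  expect_lt(f_trunc$n_samples_used, f_full$n_samples_used)
  # noiseless data: same gains either way
  expect_equal(f_trunc$k_p, f_full$k_p, tolerance = 1e-6)
  expect_equal(f_trunc$k_d, f_full$k_d, tolerance = 1e-6)
})
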