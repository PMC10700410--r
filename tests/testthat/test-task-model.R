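test_that("task configuration validates its geometry and timing", {
  cfg <- task_config()
  expect_equal(cfg$track_length / cfg$max_speed, 0.75)
  expect_equal(cfg$n_samples, 600L)
  expect_equal(cfg$dt, 1 / 60)
  expect_error(task_config(track_length = 0), "track_length")
  expect_error(task_config(max_speed = -1), "max_speed")
  expect_error(task_config(sample_rate = 0), "sample_rate")
  expect_error(task_config(trial_duration = 0), "trial_duration")
})

test_that("PD gains must be positive and finite", {
  expect_error(pd_params(0, 1), "positive")
  expect_error(pd_params(1, -2), "positive")
  expect_error(pd_params(Inf, 1), "finite")
  p <- pd_params(9, 3)
  expect_equal(p$k_p, 9)
  expect_equal(p$k_d, 3)
})

test_that("damping ratio follows k_d / (2 sqrt(k_p))", {
  expect_equal(damping_ratio(pd_params(4, 4)), 1)
  expect_equal(damping_ratio(list(k_p = 4, k_d = 0)), 0)
  expect_equal(damping_ratio(pd_params(9, 3)), 0.5)
  expect_error(damping_ratio(list(k_p = -1, k_d = 1)), "k_p > 0")
})

test_that("the goal is a fixed point of the noiseless dynamics", {
  cfg <- task_config()
  tr <- simulate_trial(pd_params(5, 3), cfg, x0 = cfg$goal, v0 = 0, noise_sd = 0)
  expect_true(all(tr$position == cfg$goal))
  expect_true(all(tr$velocity == 0))
})

test_that("identical seeds give bit-identical noisy trajectories", {
  cfg <- task_config()
  a <- simulate_trial(pd_params(8, 5), cfg, noise_sd = 2, seed = 7)
  b <- simulate_trial(pd_params(8, 5), cfg, noise_sd = 2, seed = 7)
  expect_identical(a$position, b$position)
  expect_identical(a$velocity, b$velocity)
  c <- simulate_trial(pd_params(8, 5), cfg, noise_sd = 2, seed = 8)
  expect_false(identical(a$velocity, c$velocity))
})

test_that("damping ratio >= 1 precludes overshoot from rest", {
  cfg <- task_config()
  for (zeta in c(1, 1.3, 2)) {
    for (k_p in c(2, 9, 25)) {
      p <- pd_params(k_p, 2 * sqrt(k_p) * zeta)
      tr <- simulate_trial(p, cfg, x0 = 0, v0 = 0, noise_sd = 0,
                           sample_rate_override = 600)
      expect_lte(max(tr$position), cfg$goal + 1e-6)
    }
  }
})

test_that("closed form is at equilibrium when started at the goal", {
  cfg <- task_config()
  cf <- closed_form_trajectory(pd_params(4, 2), cfg, x0 = cfg$goal, v0 = 0,
                               t = seq(0, 5, by = 0.05))
  expect_equal(cf$position, rep(cfg$goal, length(cf$position)))
  expect_equal(cf$velocity, rep(0, length(cf$velocity)))
})

test_that("critically damped closed form approaches the goal monotonically", {
  cfg <- task_config()
  t <- seq(0, 10, by = 1 / 60)
  cf <- closed_form_trajectory(pd_params(4, 4), cfg, x0 = 0, v0 = 0, t = t)
  expect_true(all(diff(cf$position) >= -1e-12))
  expect_lte(max(cf$position), cfg$goal + 1e-12)
})

test_that("all three closed-form branches match a fine-step numerical integrator", {
  skip_if_not_installed("deSolve")
  cfg <- task_config()
  t <- seq(0, 6, by = 0.01)
  cases <- list(
    underdamped = pd_params(4, 1),
    critical = pd_params(4, 4),
    overdamped = pd_params(4, 6)
  )
  for (p in cases) {
    ode_fit <- deSolve::ode(
      y = c(x = 0, v = 0), times = t,
      func = function(tt, y, parms) {
        list(c(y["v"], p$k_p * (cfg$goal - y["x"]) - p$k_d * y["v"]))
      }, parms = NULL, method = "ode45", atol = 1e-10, rtol = 1e-10
    )
    cf <- closed_form_trajectory(p, cfg, x0 = 0, v0 = 0, t = t)
    expect_lt(max(abs(cf$position - ode_fit[, "x"])), 1e-6)
    expect_lt(max(abs(cf$velocity - ode_fit[, "v"])), 1e-6)
  }
})

test_that("underdamped closed form oscillates at the damped frequency", {
  cfg <- task_config()
  p <- pd_params(4, 1)
  wd <- sqrt(p$k_p - p$k_d^2 / 4)
  t <- seq(0, 20, by = 1e-3)
  cf <- closed_form_trajectory(p, cfg, x0 = 0, v0 = 0, t = t)
  # successive zero crossings of velocity are half a damped period apart
  sgn <- sign(cf$velocity)
  crossings <- t[which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)]
  gaps <- diff(crossings)
  expect_lt(max(abs(gaps - pi / wd)), 2e-3)
})

test_that("Euler trajectories converge to the closed form at first order in dt", {
  cfg <- task_config()
  grid <- pd_grid()
  for (i in seq_len(nrow(grid))) {
    p <- pd_params(grid$k_p[i], grid$k_d[i])
    errs <- vapply(c(60, 600), function(rate) {
      tr <- simulate_trial(p, cfg, noise_sd = 0, sample_rate_override = rate)
      cf <- closed_form_trajectory(p, cfg, x0 = 0, v0 = 0, t = tr$t)
      max(abs(tr$position - cf$position))
    }, numeric(1))
    expect_lt(errs[2], errs[1]) # error decreases with dt
    # first-order scheme: a 10x finer step cuts the error ~10x
    expect_lt(errs[2], errs[1] / 8)
    expect_gt(errs[2], errs[1] / 13)
  }
  # well-damped, moderate-gain region: error below 1e-3 track lengths at 1/600
  for (k_p in c(1, 4, 9)) {
    p <- pd_params(k_p, 2 * sqrt(k_p) * 1.5)
    tr <- simulate_trial(p, cfg, noise_sd = 0, sample_rate_override = 600)
    cf <- closed_form_trajectory(p, cfg, x0 = 0, v0 = 0, t = tr$t)
    expect_lt(max(abs(tr$position - cf$position)), 1e-3)
  }
})

test_that("an unstable Euler step is reported, not silent", {
  cfg <- task_config(sample_rate = 2, trial_duration = 2)
  expect_warning(
    simulate_trial(pd_params(25, 0.1), cfg, noise_sd = 0),
    "unstable"
  )
})

test_that("trajectory invariants are enforced at construction", {
  expect_error(trial_trajectory(t = c(0, 1), position = c(0, 1, 2),
                                velocity = c(0, 0)), "equal length")
  expect_error(trial_trajectory(t = c(0, 1, 1), position = 0:2,
                                velocity = rep(0, 3)), "increasing")
  expect_error(trial_trajectory(t = 0:2, position = 0:2, velocity = rep(0, 3),
                                trial_index = 0), "trial_index")
})
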