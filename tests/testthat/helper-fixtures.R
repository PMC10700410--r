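# Shared fixtures: small, fast parameter grids and cohort specs.

# (k_p, k_d) grid spanning damping ratios 0.3..2 with k_p <= 25
pd_grid <- function() {
  grid <- expand.grid(k_p = c(1, 4, 9, 25), zeta = c(0.3, 0.5, 1, 1.5, 2))
  grid$k_d <- 2 * sqrt(grid$k_p) * grid$zeta
  grid
}

# tiny cohort spec for fast end-to-end runs; overrides win over defaults
tiny_spec <- function(...) {
  args <- list(
    n_subjects = 12, trials_per_session = 6, noise_sd = 1,
    trial_sd_log_k_p = 0.1, trial_sd_log_k_d = 0.1,
    error_rate = 0, seed = 101
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

# hand-built 4-sample trial: arbitrary positions/velocities, dt = 0.1
handmade_trial <- function() {
  trial_trajectory(
    t = c(0, 0.1, 0.2, 0.3),
    position = c(0.0, 0.05, 0.18, 0.35),
    velocity = c(0.5, 1.3, 1.7, 1.6)
  )
}
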