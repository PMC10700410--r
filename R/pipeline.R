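#' Averaged observed vs model-simulated velocity traces
#'
#' For each subject and session, averages the observed velocity across
#' trials frame by frame, and averages the velocity predicted by
#' re-simulating each trial (noiselessly) from its starting conditions
#' with that trial's fitted gains. Only valid, full-length trials enter
#' the averages. This is the standard per-subject diagnostic of how well
#' two gains summarize a session of driving.
#'
#' @param trajs Long trajectory tibble or list of [trial_trajectory()].
#' @param fits Per-trial parameter table from [fit_trajectories()].
#' @param config A [task_config()].
#' @return A tibble with columns `subject_id`, `session`, `t`,
#'   `observed`, `simulated` (mean velocities) and `n_trials`.
#' @export
average_trace_report <- function(trajs, fits, config) {
  if (is.data.frame(trajs)) trajs <- tibble_to_trajectories(trajs)
  fit_key <- paste(fits$subject_id, fits$session, fits$trial)
  rows <- lapply(trajs, function(tr) {
    i <- match(paste(tr$subject_id, tr$session, tr$trial_index), fit_key)
    if (is.na(i) || !fits$valid[i]) return(NULL)
    pred <- euler_path(fits$k_p[i], fits$k_d[i], config$goal,
                       tr$position[1], tr$velocity[1], tr$t)
    tibble::tibble(
      subject_id = tr$subject_id, session = tr$session,
      t = tr$t, observed = tr$velocity, simulated = pred$velocity
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$subject_id, .data$session, .data$t) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      observed = mean(.data$observed),
      simulated = mean(.data$simulated),
      .groups = "drop"
    )
}

#' Plot averaged observed vs simulated velocity traces
#'
#' @param traces Output of [average_trace_report()].
#' @param subjects Optional subset of subject ids to display.
#' @return A ggplot object: one panel per subject, observed and
#'   simulated mean velocity over time, coloured by session.
#' @export
plot_trace_report <- function(traces, subjects = NULL) {
  if (!is.null(subjects)) {
    traces <- traces[traces$subject_id %in% subjects, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(traces, c("observed", "simulated"),
                              names_to = "source", values_to = "velocity")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$t, y = .data$velocity,
    colour = factor(.data$session), linetype = .data$source
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "time (s)", y = "mean velocity (track units/s)",
                  colour = "session", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on either a synthetic cohort or CSV
#' inputs: (simulate or read) trajectories -> per-trial PD fits ->
#' session summaries -> reliability report (both split schemes, Fisher z
#' session comparisons, across-session ICC(3,1)) -> standardized-beta
#' association models -> averaged velocity-trace report. Stages that
#' cannot run (e.g. reliability with a single subject) are skipped with
#' a recorded notice rather than failing the run.
#'
#' @param spec A [cohort_spec()] used to simulate data when no
#'   `trajectories_path` is given.
#' @param config A [task_config()].
#' @param trajectories_path,covariates_path Optional CSV inputs; when
#'   given, they replace simulation.
#' @param out_dir Optional output directory; when given, all tables are
#'   written as CSVs (`parameter_fits.csv`, `session_summaries.csv`,
#'   `reliability_report.csv`, `association_results.csv`,
#'   `trace_report.csv`) plus a `manifest.json`-style run log
#'   (`manifest.csv`).
#' @param exclude_same_day,exclude_non_mobile Exclusion toggles passed to
#'   the reliability and association stages.
#' @param truncate_post_stop Passed to [fit_trajectories()].
#' @param overwrite Allow replacing existing output files.
#' @return A list bundle: `trajectories`, `covariates`, `fits`,
#'   `summaries`, `reliability`, `association` (list per session),
#'   `traces`, `notices` (character), `manifest`.
#' @export
run_pipeline <- function(spec = cohort_spec(), config = task_config(),
                         trajectories_path = NULL, covariates_path = NULL,
                         out_dir = NULL,
                         exclude_same_day = FALSE, exclude_non_mobile = FALSE,
                         truncate_post_stop = FALSE, overwrite = FALSE) {
  notices <- character()

  if (is.null(trajectories_path)) {
    sim <- simulate_cohort(spec, config)
    trajectories <- sim$trajectories
    covariates <- sim$cohort
  } else {
    trajectories <- read_trajectories(trajectories_path)
    covariates <- if (!is.null(covariates_path)) read_covariates(covariates_path) else NULL
  }

  fits <- fit_trajectories(trajectories, config,
                           truncate_post_stop = truncate_post_stop)
  summaries <- summarize_sessions(fits)

  reliability <- withCallingHandlers(
    reliability_report(fits, covariates,
                       exclude_same_day = exclude_same_day,
                       exclude_non_mobile = exclude_non_mobile),
    warning = function(w) {
      notices <<- c(notices, paste("reliability:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  if (!nrow(reliability)) {
    notices <- c(notices, "reliability: stage skipped (insufficient subjects)")
  }

  association <- list()
  if (!is.null(covariates)) {
    cohort_table <- dplyr::inner_join(summaries, covariates, by = "subject_id")
    for (ses in sort(unique(summaries$session))) {
      res <- tryCatch(
        run_association_suite(cohort_table, session = ses,
                              exclude_same_day = exclude_same_day,
                              exclude_non_mobile = exclude_non_mobile),
        error = function(e) {
          notices <<- c(notices,
                        sprintf("association (session %d): %s", ses,
                                conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(res)) association[[paste0("session", ses)]] <- res
    }
  } else {
    notices <- c(notices, "association: stage skipped (no covariates)")
  }

  traces <- average_trace_report(trajectories, fits, config)

  manifest <- tibble::tibble(
    package_version = as.character(utils::packageVersion("pdrive")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = if (is.null(trajectories_path)) spec$seed else NA_integer_,
    spec_hash = rlang::hash(spec),
    config_hash = rlang::hash(unclass(config)),
    n_trials = nrow(fits),
    n_valid_trials = sum(fits$valid)
  )

  bundle <- list(
    trajectories = trajectories, covariates = covariates, fits = fits,
    summaries = summaries, reliability = reliability,
    association = association, traces = traces,
    notices = notices, manifest = manifest
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    save_csv <- function(x, name) {
      p <- file.path(out_dir, name)
      if (file.exists(p) && !overwrite) {
        stop("output exists; pass overwrite = TRUE: ", p, call. = FALSE)
      }
      readr::write_csv(x, p)
    }
    save_csv(fits, "parameter_fits.csv")
    save_csv(summaries, "session_summaries.csv")
    save_csv(reliability, "reliability_report.csv")
    if (length(association)) {
      assoc_all <- dplyr::bind_rows(association, .id = "session_label")
      save_csv(assoc_all, "association_results.csv")
    }
    save_csv(traces, "trace_report.csv")
    save_csv(manifest, "manifest.csv")
    if (length(notices)) {
      writeLines(notices, file.path(out_dir, "run_log.txt"))
    }
  }

  bundle
}
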