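trajectory_cols <- c("subject_id", "session", "block", "trial",
                     "t", "position", "velocity",
                     "terminated_with_error", "restart_count")

#' Convert between trajectory objects and the long table layout
#'
#' The on-disk layout is one row per frame with columns `subject_id`,
#' `session`, `block`, `trial`, `t`, `position`, `velocity`,
#' `terminated_with_error`, `restart_count`.
#'
#' @param trajs A list of [trial_trajectory()] objects.
#' @return `trajectories_to_tibble()`: the long tibble;
#'   `tibble_to_trajectories()`: a list of `trial_trajectory` objects.
#' @export
trajectories_to_tibble <- function(trajs) {
  dplyr::bind_rows(lapply(trajs, function(tr) {
    tibble::tibble(
      subject_id = tr$subject_id, session = tr$session, block = tr$block,
      trial = tr$trial_index, t = tr$t,
      position = tr$position, velocity = tr$velocity,
      terminated_with_error = tr$terminated_with_error,
      restart_count = tr$restart_count
    )
  }))
}

#' @rdname trajectories_to_tibble
#' @param tbl A long trajectory tibble with the standard columns.
#' @export
tibble_to_trajectories <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  missing_cols <- setdiff(trajectory_cols, names(tbl))
  if (length(missing_cols)) {
    stop("missing trajectory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(tbl$subject_id, tbl$session, tbl$trial, drop = TRUE)
  groups <- split(seq_len(nrow(tbl)), key)
  out <- lapply(groups, function(idx) {
    g <- tbl[idx, ]
    trial_trajectory(
      t = g$t, position = g$position, velocity = g$velocity,
      subject_id = g$subject_id[1], session = g$session[1],
      block = g$block[1], trial_index = g$trial[1],
      terminated_with_error = g$terminated_with_error[1],
      restart_count = g$restart_count[1]
    )
  })
  unname(out)
}

#' Write trajectories to the standard CSV layout
#'
#' @param trajs A long trajectory tibble or a list of
#'   [trial_trajectory()] objects.
#' @param path Output file path.
#' @param overwrite Allow replacing an existing file (default `FALSE`).
#' @return The path, invisibly.
#' @export
write_trajectories <- function(trajs, path, overwrite = FALSE) {
  if (!is.data.frame(trajs)) trajs <- trajectories_to_tibble(trajs)
  if (file.exists(path) && !overwrite) {
    stop("file exists; pass overwrite = TRUE to replace: ", path, call. = FALSE)
  }
  readr::write_csv(trajs[trajectory_cols], path)
  invisible(path)
}

#' Read trajectories from the standard CSV layout
#'
#' Validates structure while loading: the header must contain every
#' standard column, and each trial's time stamps must be strictly
#' increasing. A trial failing the time check is dropped with a warning
#' naming the file lines it occupies; well-formed trials still load.
#'
#' @param path CSV file path.
#' @param as_list Return a list of [trial_trajectory()] objects instead
#'   of the long tibble.
#' @return The long trajectory tibble (default) or a list of
#'   trajectories.
#' @export
read_trajectories <- function(path, as_list = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      session = readr::col_integer(),
      block = readr::col_integer(),
      trial = readr::col_integer(),
      t = readr::col_double(),
      position = readr::col_double(),
      velocity = readr::col_double(),
      terminated_with_error = readr::col_logical(),
      restart_count = readr::col_integer()
    )
  )
  missing_cols <- setdiff(trajectory_cols, names(tbl))
  if (length(missing_cols)) {
    stop("missing trajectory columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(tbl)) {
    warning("empty trajectory file: ", path, call. = FALSE)
    return(if (as_list) list() else tbl)
  }
  key <- interaction(tbl$subject_id, tbl$session, tbl$trial, drop = TRUE)
  bad <- unlist(lapply(split(seq_len(nrow(tbl)), key), function(idx) {
    if (any(diff(tbl$t[idx]) <= 0)) idx else integer(0)
  }))
  if (length(bad)) {
    # +1 for the header row: report 1-based file line numbers
    lines <- range(bad + 1L)
    warning(sprintf(
      "dropped %d trial(s) with non-increasing time stamps (file lines %d-%d)",
      length(unique(key[bad])), lines[1], lines[2]
    ), call. = FALSE)
    tbl <- tbl[-bad, , drop = FALSE]
  }
  if (as_list) tibble_to_trajectories(tbl) else tbl
}

#' Write and read the per-subject covariate table
#'
#' @param covariates A covariate tibble (see [sample_cohort()]).
#' @param path CSV file path.
#' @param overwrite Allow replacing an existing file.
#' @return The path (write) or a tibble (read).
#' @export
write_covariates <- function(covariates, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("file exists; pass overwrite = TRUE to replace: ", path, call. = FALSE)
  }
  readr::write_csv(covariates, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  col_types = readr::cols()))
  if (!"subject_id" %in% header) {
    stop("covariate table must have a subject_id column", call. = FALSE)
  }
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_guess()
  ))
}
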