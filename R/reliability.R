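#' Trial-splitting schemes for split-half reliability
#'
#' Two schemes are supported. `odd_even` assigns trials by parity of
#' their trial index (odd-numbered trials form half 1). `first_second`
#' splits the valid trials of a session at the midpoint of their order;
#' when the count is odd, the middle trial goes to the first half.
#'
#' @param name `"odd_even"` or `"first_second"`.
#' @return A `split_scheme` object with a `$assign` function mapping a
#'   vector of trial indices (one subject-session's valid trials) to
#'   halves 1/2.
#' @examples
#' split_scheme("odd_even")$assign(c(1, 2, 3, 4, 5))   # 1 2 1 2 1
#' split_scheme("first_second")$assign(c(1, 2, 3, 4, 5)) # 1 1 1 2 2
#' @export
split_scheme <- function(name = c("odd_even", "first_second")) {
  name <- match.arg(name)
  assign_fun <- switch(
    name,
    odd_even = function(trial_index) {
      ifelse(trial_index %% 2 == 1, 1L, 2L)
    },
    first_second = function(trial_index) {
      rk <- rank(trial_index, ties.method = "first")
      ifelse(rk <= ceiling(length(trial_index) / 2), 1L, 2L)
    }
  )
  structure(list(name = name, assign = assign_fun), class = "split_scheme")
}

#' @export
print.split_scheme <- function(x, ...) {
  cat(sprintf("<split_scheme> %s\n", x$name))
  invisible(x)
}

#' Split-half Pearson correlation across subjects
#'
#' Correlates the two half-session estimates of a parameter across
#' subjects (e.g. mean log K_p from odd trials vs from even trials) and
#' returns the Pearson r with a two-sided p-value.
#'
#' @param half1,half2 Per-subject parameter estimates from the two
#'   halves, aligned by subject. Pairs with a missing value are dropped.
#' @return A list with `r`, `n` (pairs used) and `p`.
#' @export
split_half_correlation <- function(half1, half2) {
  ok <- is.finite(half1) & is.finite(half2)
  x <- half1[ok]
  y <- half2[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 subjects with both halves", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance across subjects in one half", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = n, p = ct$p.value)
}

#' Compare two independent correlations via Fisher's z
#'
#' Tests whether two correlations estimated on independent samples
#' differ: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' with a two-sided normal p-value.
#'
#' @param r1,r2 The two sample correlations (strictly inside (-1, 1)).
#' @param n1,n2 The sample sizes behind each correlation (> 3).
#' @return A list with `z` and `p`.
#' @examples
#' fisher_z_compare(0.95, 89, 0.92, 66)
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(is.finite(r1), is.finite(r2), n1 > 3, n2 > 3)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    warning("|r| = 1: Fisher transform is infinite", call. = FALSE)
    z <- sign(atanh(pmin(pmax(r1, -1), 1) * (1 - 1e-16)) -
                atanh(pmin(pmax(r2, -1), 1) * (1 - 1e-16))) * Inf
    if (r1 == r2) z <- 0
    return(list(z = z, p = if (is.infinite(z)) 0 else 1))
  }
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (atanh(r1) - atanh(r2)) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Test-retest intraclass correlation ICC(3,1)
#'
#' The two-way mixed, consistency, single-rater intraclass correlation:
#' sessions are treated as fixed "raters", so a constant shift between
#' sessions does not reduce the coefficient. With `k` sessions,
#' `ICC = (MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`
#' where the mean squares come from the two-way (subject x session)
#' ANOVA decomposition. The p-value is from the one-sided F test of
#' `MS_subjects / MS_error` against ICC = 0.
#'
#' @param session1,session2 Per-subject parameter values from the two
#'   sessions, aligned by subject. Pairs with missing values are dropped.
#' @return A list with `icc`, `n` (complete pairs), `df1`, `df2`, `F`
#'   and `p`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30)
#' icc3(x, x + 0.5)$icc # 1: consistency ignores a fixed shift
#' @export
icc3 <- function(session1, session2) {
  ok <- is.finite(session1) & is.finite(session2)
  y <- cbind(session1[ok], session2[ok])
  n <- nrow(y)
  k <- ncol(y)
  if (n < 5) stop("need at least 5 complete subject pairs", call. = FALSE)

  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  ss_total <- sum((y - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols

  if (ss_rows <= 0) stop("zero between-subject variance", call. = FALSE)

  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))

  icc <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  f <- ms_rows / ms_err
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, n = n, df1 = n - 1, df2 = (n - 1) * (k - 1), F = f, p = p)
}

#' Full reliability report for a fitted cohort
#'
#' Computes the complete reliability grid from a per-trial parameter
#' table: split-half Pearson correlations for both log parameters, both
#' sessions and both split schemes (8 rows); Fisher z comparisons of the
#' session-1 vs session-2 split-half correlations per parameter and
#' scheme (4 rows); and across-session ICC(3,1) per parameter (2 rows),
#' computed on subjects with valid summaries in both sessions.
#'
#' @param fits Per-trial parameter table from [fit_trajectories()].
#' @param covariates Optional covariate table (see [sample_cohort()])
#'   used for the exclusion toggles.
#' @param exclude_same_day Drop subjects who completed both sessions on
#'   the same day (requires `covariates$same_day_sessions`).
#' @param exclude_non_mobile Drop subjects who did not use a mobile
#'   device (requires `covariates$device_mobile`).
#' @param min_subjects Minimum subjects required for any statistic;
#'   below this the report is empty with a warning.
#' @return A tibble with columns `statistic` (`split_half`, `fisher_z`,
#'   `icc3`), `parameter`, `scheme`, `session`, `estimate`, `n`, `n2`
#'   and `p`.
#' @export
reliability_report <- function(fits, covariates = NULL,
                               exclude_same_day = FALSE,
                               exclude_non_mobile = FALSE,
                               min_subjects = 4) {
  stopifnot(is.data.frame(fits))

  if (exclude_same_day || exclude_non_mobile) {
    if (is.null(covariates)) {
      stop("exclusion toggles require a covariate table", call. = FALSE)
    }
    keep <- rep(TRUE, nrow(covariates))
    if (exclude_same_day) keep <- keep & !as.logical(covariates$same_day_sessions)
    if (exclude_non_mobile) keep <- keep & as.logical(covariates$device_mobile)
    fits <- dplyr::semi_join(
      fits, dplyr::filter(covariates, keep)["subject_id"], by = "subject_id"
    )
  }

  n_sub <- length(unique(fits$subject_id[fits$valid]))
  empty <- tibble::tibble(
    statistic = character(), parameter = character(), scheme = character(),
    session = integer(), estimate = numeric(), n = integer(),
    n2 = integer(), p = numeric()
  )
  if (n_sub < min_subjects) {
    warning(sprintf("insufficient subjects for reliability (%d < %d); empty report",
                    n_sub, min_subjects), call. = FALSE)
    return(empty)
  }

  params <- c("log_k_p", "log_k_d")
  sessions <- sort(unique(fits$session))
  rows <- list()

  sh <- list()
  for (scheme_name in c("odd_even", "first_second")) {
    halves <- summarize_halves(fits, split_scheme(scheme_name))
    for (par in params) {
      col <- paste0("mean_", par)
      for (ses in sessions) {
        wide <- halves |>
          dplyr::filter(.data$session == ses) |>
          dplyr::select("subject_id", "half", dplyr::all_of(col)) |>
          tidyr::pivot_wider(names_from = "half", values_from = dplyr::all_of(col),
                             names_prefix = "h")
        if (!all(c("h1", "h2") %in% names(wide))) next
        res <- tryCatch(split_half_correlation(wide$h1, wide$h2),
                        error = function(e) NULL)
        if (is.null(res)) next
        key <- paste(scheme_name, par, ses, sep = ".")
        sh[[key]] <- res
        rows[[length(rows) + 1L]] <- tibble::tibble(
          statistic = "split_half", parameter = par, scheme = scheme_name,
          session = as.integer(ses), estimate = res$r, n = res$n,
          n2 = NA_integer_, p = res$p
        )
      }
    }
  }

  if (length(sessions) >= 2) {
    for (scheme_name in c("odd_even", "first_second")) {
      for (par in params) {
        k1 <- paste(scheme_name, par, sessions[1], sep = ".")
        k2 <- paste(scheme_name, par, sessions[2], sep = ".")
        if (is.null(sh[[k1]]) || is.null(sh[[k2]])) next
        fz <- fisher_z_compare(sh[[k1]]$r, sh[[k1]]$n, sh[[k2]]$r, sh[[k2]]$n)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          statistic = "fisher_z", parameter = par, scheme = scheme_name,
          session = NA_integer_, estimate = fz$z,
          n = sh[[k1]]$n, n2 = sh[[k2]]$n, p = fz$p
        )
      }
    }

    summaries <- summarize_sessions(fits)
    for (par in params) {
      col <- paste0("mean_", par)
      wide <- summaries |>
        dplyr::filter(!.data$missing) |>
        dplyr::select("subject_id", "session", dplyr::all_of(col)) |>
        tidyr::pivot_wider(names_from = "session", values_from = dplyr::all_of(col),
                           names_prefix = "s")
      s1 <- paste0("s", sessions[1])
      s2 <- paste0("s", sessions[2])
      if (!all(c(s1, s2) %in% names(wide))) next
      res <- tryCatch(icc3(wide[[s1]], wide[[s2]]), error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        statistic = "icc3", parameter = par, scheme = NA_character_,
        session = NA_integer_, estimate = res$icc, n = res$n,
        n2 = NA_integer_, p = res$p
      )
    }
  }

  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}
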