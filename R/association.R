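#' Standardized-coefficient linear regression
#'
#' Fits an ordinary least-squares model after z-scoring the outcome and
#' every predictor (binary predictors included), so the reported
#' coefficients are standardized betas. Incomplete cases are dropped
#' listwise before scaling.
#'
#' @param data A data frame holding outcome and predictor columns.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @return A tibble with one row per predictor: `outcome`, `predictor`,
#'   `beta` (standardized coefficient), `se` (its standard error), `p`
#'   (two-sided), `n` (complete cases used).
#' @examples
#' d <- data.frame(y = rnorm(50))
#' d$x <- d$y # perfectly collinear single predictor
#' standardized_lm(d, "y", "x") # beta = 1
#' @export
standardized_lm <- function(data, outcome, predictors) {
  stopifnot(is.data.frame(data), length(predictors) >= 1)
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < length(predictors) + 2) {
    stop("too few complete cases for the number of predictors", call. = FALSE)
  }
  sds <- vapply(d, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(names(sds)[sds == 0], collapse = ", "), call. = FALSE)
  }
  dz <- as.data.frame(lapply(d, function(col) as.numeric(scale(col))))
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = dz)
  if (fit$rank < length(predictors) + 1) {
    stop("rank-deficient design (collinear predictors)", call. = FALSE)
  }
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  tibble::tibble(
    outcome = outcome,
    predictor = rownames(co),
    beta = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    p = unname(co[, "Pr(>|t|)"]),
    n = n
  )
}

#' The cohort-level association model set
#'
#' Fits the standard battery of standardized-coefficient regressions on
#' one session's data: each of the four outcomes (mean log K_p, mean log
#' K_d, mean final car position, log error-trial count) on the full
#' covariate set (PANAS-X fear, age, male gender, bachelor's-or-higher
#' education), plus demographics-only variants of the two parameter
#' models (age, gender, education without fear). No multiple-testing
#' correction is applied; the number of models fitted is attached as the
#' `n_models` attribute. Models that cannot be fit (e.g. a zero-variance
#' outcome such as the error count in an error-free cohort) are skipped
#' and reported in the `failures` attribute; if every model fails, an
#' error is raised with the collected diagnoses.
#'
#' @param cohort A per-subject table joining session summaries (columns
#'   `mean_log_k_p`, `mean_log_k_d`, `final_position_mean`,
#'   `log_error_trial_count`, `session`) with covariates (`fear`, `age`,
#'   `gender_male`, `education_bachelor_plus`, and the exclusion flags).
#'   Typically `dplyr::inner_join(summarize_sessions(fits), covariates)`.
#' @param session Which session's summaries to analyse (default 1).
#' @param exclude_same_day,exclude_non_mobile Exclusion toggles mirroring
#'   the reliability sensitivity analyses.
#' @return A tibble of model results (one row per outcome x model x
#'   predictor) with columns `outcome`, `model` (`"fear_adjusted"` or
#'   `"demographics"`), `predictor`, `beta`, `se`, `p`, `n`.
#' @export
run_association_suite <- function(cohort, session = 1,
                                  exclude_same_day = FALSE,
                                  exclude_non_mobile = FALSE) {
  stopifnot(is.data.frame(cohort))
  d <- cohort
  if ("session" %in% names(d)) d <- d[d$session == session, , drop = FALSE]
  if (exclude_same_day) d <- d[!as.logical(d$same_day_sessions), , drop = FALSE]
  if (exclude_non_mobile) d <- d[as.logical(d$device_mobile), , drop = FALSE]
  if (!nrow(d)) stop("empty cohort after exclusions", call. = FALSE)

  demo <- c("age", "gender_male", "education_bachelor_plus")
  full <- c("fear", demo)
  outcomes <- c("mean_log_k_p", "mean_log_k_d",
                "final_position_mean", "log_error_trial_count")

  specs <- list()
  for (oc in outcomes) {
    specs[[length(specs) + 1L]] <- list(outcome = oc, predictors = full,
                                        model = "fear_adjusted")
  }
  for (oc in c("mean_log_k_p", "mean_log_k_d")) {
    specs[[length(specs) + 1L]] <- list(outcome = oc, predictors = demo,
                                        model = "demographics")
  }

  failures <- character()
  rows <- lapply(specs, function(sp) {
    res <- tryCatch(standardized_lm(d, sp$outcome, sp$predictors),
                    error = function(e) {
                      failures <<- c(failures, sprintf(
                        "%s (%s): %s", sp$outcome, sp$model, conditionMessage(e)
                      ))
                      NULL
                    })
    if (!is.null(res)) res$model <- sp$model
    res
  })
  if (all(vapply(rows, is.null, logical(1)))) {
    stop("all association models failed:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("outcome", "model", "predictor", "beta", "se", "p", "n")]
  attr(out, "n_models") <- length(specs)
  attr(out, "failures") <- failures
  out
}
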