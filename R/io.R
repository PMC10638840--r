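#' Read / write panel data CSV
#'
#' Panel CSV schema: comma-separated, UTF-8, mandatory header, columns
#' `subject_id`, `time_years`, `state` (NC/aMCI/AD) and one column per
#' covariate; one row per visit.  Schema violations are reported with the
#' offending row or column.
#'
#' @param path file path.
#' @param covariates covariate column names expected in the file; by
#'   default every column beyond the required ones (and `group`).
#' @return A [panel_dataset()].
#' @export
read_panel_csv <- function(path, covariates = NULL) {
  header <- utils::read.csv(path, nrows = 1L, check.names = FALSE)
  req <- c("subject_id", "time_years", "state")
  if (!all(req %in% names(header)))
    stop("panel CSV missing required header column(s): ",
         paste(setdiff(req, names(header)), collapse = ", "))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(covariates))
    covariates <- setdiff(names(d), c(req, "group"))
  panel_dataset(d, covariates = covariates)
}

#' @rdname read_panel_csv
#' @param panel a [panel_dataset()].
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read / write tract-profile data
#'
#' Long CSV schema: `subject_id`, `tract`, `metric` (FA/MD), `node`
#' (0-based integer), `value`, `tracked` (0/1), plus optional demographic
#' columns (`group`, `age`, `sex`).  The JSON layout is the same table in
#' column-oriented form.
#'
#' @param path file path.
#' @return A `tract_profile_set` data.frame.
#' @export
read_tract_profiles_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_profiles(d)
}

#' @rdname read_tract_profiles_csv
#' @param profiles a `tract_profile_set`.
#' @export
write_tract_profiles_csv <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tract_profiles_csv
#' @export
read_tract_profiles_json <- function(path) {
  d <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_profiles(d)
}

#' @rdname read_tract_profiles_csv
#' @export
write_tract_profiles_json <- function(profiles, path) {
  jsonlite::write_json(as.list(as.data.frame(profiles)), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

validate_profiles <- function(d) {
  req <- c("subject_id", "tract", "metric", "node", "value", "tracked")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("tract-profile data missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!d$metric %in% c("FA", "MD"))
  if (length(bad)) stop("invalid metric at row ", bad[1L], ": '", d$metric[bad[1L]], "'")
  if (any(d$node != round(d$node) | d$node < 0))
    stop("node indices must be nonnegative integers (0-based)")
  structure(d, class = c("tract_profile_set", "data.frame"))
}

#' Write a model fit as JSON
#'
#' Serializes an `msm_fit`: parameters per transition, standard errors,
#' log-likelihood and the convergence block.
#'
#' @param fit an `msm_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    rates = as.list(fit$model$r0),
    beta = if (ncol(fit$model$beta)) as.data.frame(fit$model$beta) else NULL,
    covariates = fit$model$covariates,
    se = as.list(fit$se),
    loglik = fit$loglik,
    n_subjects = fit$n_subjects,
    n_intervals = fit$n_intervals,
    convergence = fit$convergence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file has a `seed` (mandatory), a `cohort:` section mapping to
#' [cohort_config()] arguments and a `profiles:` section mapping to
#' [profile_config()] arguments; unspecified fields take the package
#' defaults.  Stage seeds are derived from the global seed.
#'
#' @param path YAML file path.
#' @return Object of class `pipeline_config`: list with `cohort`,
#'   `profiles`, `seed` and the remaining settings (`test`, `metric_alpha`,
#'   `folds`, `max_failure_fraction`).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("pipeline config must set a seed")
  pipeline_config(seed = y$seed, cohort = y$cohort %||% list(),
                  profiles = y$profiles %||% list(),
                  test = y$test %||% "anova",
                  alpha = y$alpha %||% 0.05,
                  folds = y$folds %||% 5L,
                  max_failure_fraction = y$max_failure_fraction %||% 0.25)
}

#' Pipeline configuration
#'
#' @param seed global integer seed; every stage seed derives from it.
#' @param cohort,profiles lists of overrides for [cohort_config()] /
#'   [profile_config()] (their `seed` fields are set from the global seed).
#' @param test pointwise test name for the tract-statistics stage.
#' @param alpha per-node significance level.
#' @param folds cross-validation folds.
#' @param max_failure_fraction tract-exclusion threshold.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, cohort = list(), profiles = list(),
                            test = "anova", alpha = 0.05, folds = 5L,
                            max_failure_fraction = 0.25) {
  seed <- as.integer(seed)
  cohort$seed <- seed
  profiles$seed <- seed + 1L
  structure(list(cohort = do.call(cohort_config, cohort),
                 profiles = do.call(profile_config, profiles),
                 seed = seed, test = test, alpha = alpha,
                 folds = as.integer(folds),
                 max_failure_fraction = max_failure_fraction),
            class = "pipeline_config")
}
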