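#' Run the full synthetic analysis pipeline
#'
#' Chains the four stages end to end on a synthetic cohort:
#' 1. simulate — generate the panel cohort and tract profiles, write
#'    `panel.csv`, `profiles.csv` and the per-group summary table;
#' 2. fit — maximum-likelihood fit of the progression model, write
#'    `fit.json`;
#' 3. tractstats — tract exclusion by tracking failure, then the pointwise
#'    group test per retained tract and metric, write `node_results.csv`
#'    and `tract_exclusion.json`;
#' 4. evaluate — multimodal feature table (mm + dti blocks) and stratified
#'    cross-validated AD-vs-NC classification, write `metrics.json` and
#'    `roc_points.csv`.
#'
#' Every stage draws its randomness from a seed derived from the global
#' config seed, so rerunning with the same config reproduces every output
#' file hash.  A failing stage halts the pipeline with the stage named;
#' files already written are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Manifest list (also written to `manifest.json`): per-file md5
#'   hashes, the seed, and per-stage status.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------
  cohort <- stage("simulate", generate_cohort(config$cohort))
  first <- cohort[!duplicated(cohort$subject_id), , drop = FALSE]
  groups <- stats::setNames(first$group, first$subject_id)
  demo <- first[, c("subject_id", "age", "sex")]
  profiles <- stage("simulate",
                    generate_tract_profiles(config$profiles, groups, demo))
  f_panel <- file.path(out_dir, "panel.csv")
  f_prof <- file.path(out_dir, "profiles.csv")
  f_summary <- file.path(out_dir, "summary_table.csv")
  write_panel_csv(cohort, f_panel)
  write_tract_profiles_csv(profiles, f_prof)
  utils::write.csv(generate_summary_table(cohort), f_summary, row.names = FALSE)
  files <- c(files, f_panel, f_prof, f_summary)

  # -- fit --------------------------------------------------------------
  fit <- stage("fit", fit_msm(cohort))
  f_fit <- file.path(out_dir, "fit.json")
  write_fit_json(fit, f_fit)
  files <- c(files, f_fit)

  # -- tractstats -------------------------------------------------------
  excl <- stage("tractstats",
                exclude_untrackable_tracts(profiles, config$max_failure_fraction))
  node_res <- stage("tractstats", {
    res <- list()
    for (tract in excl$retained)
      for (metric in c("FA", "MD")) {
        r <- pointwise_profile_test(profiles, tract, metric,
                                    test = config$test, alpha = config$alpha)
        r$tract <- tract; r$metric <- metric
        res[[length(res) + 1L]] <- as.data.frame(r)
      }
    do.call(rbind, res)
  })
  f_nodes <- file.path(out_dir, "node_results.csv")
  f_excl <- file.path(out_dir, "tract_exclusion.json")
  utils::write.csv(node_res[, c("tract", "metric", "node", "statistic",
                                "df1", "df2", "p", "significant")],
                   f_nodes, row.names = FALSE)
  jsonlite::write_json(excl, f_excl, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f_nodes, f_excl)

  # -- evaluate ---------------------------------------------------------
  eval_res <- stage("evaluate", {
    keep <- groups %in% c("NC", "AD")
    ft <- build_feature_table(factor(groups[keep], levels = c("NC", "AD")),
                              blocks = c("mm", "dti"), fit = fit,
                              panel = cohort, profiles = profiles,
                              retained_tracts = excl$retained)
    cross_validated_eval(ft, folds = config$folds, seed = config$seed + 2L)
  })
  f_metrics <- file.path(out_dir, "metrics.json")
  f_roc <- file.path(out_dir, "roc_points.csv")
  jsonlite::write_json(list(auc = eval_res$roc$auc,
                            metrics = as.list(eval_res$metrics),
                            confusion = unclass(eval_res$cm)),
                       f_metrics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(eval_res$roc$points, f_roc, row.names = FALSE)
  files <- c(files, f_metrics, f_roc)

  manifest <- list(seed = config$seed,
                   files = as.list(tools::md5sum(files)),
                   stages = c("simulate", "fit", "tractstats", "evaluate"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
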