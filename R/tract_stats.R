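#' Classic one-way ANOVA
#'
#' The equal-variance F test: the between-group mean square (sum of
#' `n_i * (xbar_i - xbar)^2` over `k - 1`) over the pooled error mean
#' square (within sum of squares over `N - k`), referred to the
#' F(k - 1, N - k) upper tail.
#'
#' @param groups list of numeric vectors, one per group, each of length
#'   two or more.
#' @return List of class `group_test`: `statistic`, `df1`, `df2`,
#'   `p.value`, `method`.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
anova_oneway <- function(groups) {
  check_groups(groups)
  n <- lengths(groups)
  k <- length(groups); N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  gm <- sum(n * means) / N
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw == 0) {
    stat <- if (ssb == 0) 0 else Inf
  } else stat <- (ssb / (k - 1)) / (ssw / (N - k))
  group_test(stat, k - 1, N - k, "One-way ANOVA (equal variances)")
}

#' One-way ANOVA from group summary statistics
#'
#' Algebraically identical to [anova_oneway()], but computed from per-group
#' (n, mean, sd) triplets: the between sum of squares needs only sizes and
#' means, and the within sum of squares is `sum((n_i - 1) * sd_i^2)`.  This
#' is the test that recomputes a published summary table's p-values.
#'
#' @param n,mean,sd numeric vectors of group sizes (>= 2), means, and
#'   standard deviations (>= 0).
#' @return As [anova_oneway()].
#' @export
#' @examples
#' # age row of a three-group demographic table
#' anova_from_summaries(n = c(34, 47, 39), mean = c(69.5, 69.7, 68.5),
#'                      sd = c(8.8, 9.3, 7.1))
anova_from_summaries <- function(n, mean, sd) {
  if (length(n) < 2L) stop("need at least two groups")
  if (any(n < 2L)) stop("every group needs n >= 2")
  if (any(sd < 0)) stop("standard deviations must be nonnegative")
  if (length(mean) != length(n) || length(sd) != length(n))
    stop("n, mean, sd must have equal length")
  k <- length(n); N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  stat <- if (ssw == 0) { if (ssb == 0) 0 else Inf }
          else (ssb / (k - 1)) / (ssw / (N - k))
  group_test(stat, k - 1, N - k, "One-way ANOVA from summary statistics")
}

#' Welch heteroscedastic one-way test
#'
#' The standard Welch statistic: groups are weighted by `w_i = n_i / s_i^2`,
#' the numerator is the weighted between-group mean square about the
#' weighted grand mean, and the denominator applies the Welch correction;
#' the reference distribution is F with `k - 1` and a fractional
#' Satterthwaite-type denominator df.  Valid under unequal group variances,
#' where the classic test is not.
#'
#' @inheritParams anova_oneway
#' @return As [anova_oneway()] (`df2` fractional).
#' @export
welch_anova <- function(groups) {
  check_groups(groups)
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("Welch test undefined with zero within-group variance")
  n <- lengths(groups); k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  w <- n / v
  W <- sum(w)
  mw <- sum(w * means) / W
  A <- sum(w * (means - mw)^2) / (k - 1)
  tmp <- sum((1 - w / W)^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * tmp
  df2 <- (k^2 - 1) / (3 * tmp)
  group_test(A / B, k - 1, df2, "Welch heteroscedastic one-way test")
}

#' Brown-Forsythe heteroscedastic one-way test
#'
#' The Brown-Forsythe statistic
#' `S* = sum(n_i (xbar_i - xbar)^2) / sum((1 - n_i/N) s_i^2)`, referred to
#' F(k - 1, f) where the denominator df `f` follows the Satterthwaite form
#' `1/f = sum(c_i^2 / (n_i - 1))` with
#' `c_i = (1 - n_i/N) s_i^2 / sum((1 - n_j/N) s_j^2)`.  In a balanced
#' design with equal group variances it reduces to the classic F.
#'
#' @inheritParams anova_oneway
#' @return As [anova_oneway()] (`df2` fractional).
#' @export
brown_forsythe <- function(groups) {
  check_groups(groups)
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("Brown-Forsythe test undefined with zero within-group variance")
  n <- lengths(groups); k <- length(groups); N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  gm <- sum(n * means) / N
  num <- sum(n * (means - gm)^2)
  dvec <- (1 - n / N) * v
  den <- sum(dvec)
  cvec <- dvec / den
  df2 <- 1 / sum(cvec^2 / (n - 1))
  group_test(num / den, k - 1, df2, "Brown-Forsythe heteroscedastic one-way test")
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  if (any(lengths(groups) < 2L))
    stop("every group needs at least two values")
  invisible(groups)
}

group_test <- function(stat, df1, df2, method) {
  p <- if (is.infinite(stat)) 0 else stats::pf(stat, df1, df2, lower.tail = FALSE)
  structure(list(statistic = stat, df1 = df1, df2 = df2,
                 p.value = p, method = method),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f, df = (%.4g, %.4g), p = %.4g\n",
              x$statistic, x$df1, x$df2, x$p.value))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' The test behind a demographic table's sex-by-group p-value: Pearson's
#' chi-square on an r x c count table, without continuity correction, with
#' df = (r - 1)(c - 1).
#'
#' @param table matrix of nonnegative counts with positive margins.
#' @return List of class `group_test` with `statistic` (chi-square), `df1`
#'   (the df), `df2 = NA`, `p.value`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(13, 21, 20, 27, 18, 21), nrow = 2))
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  ct <- stats::chisq.test(table, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), df1 = unname(ct$parameter),
                 df2 = NA_real_, p.value = ct$p.value,
                 method = "Pearson chi-square test of independence"),
            class = "group_test")
}

#' Residualize values on age and sex
#'
#' Linear covariate adjustment before group testing: ordinary least squares
#' of the values on an intercept, age and sex; the residuals are returned
#' re-centered to the grand mean, so the adjusted values carry the original
#' overall level but no linear age/sex trend.
#'
#' @param values numeric vector.
#' @param age,sex numeric vectors aligned with `values`.
#' @return Adjusted values, same length as `values`.
#' @export
adjust_covariates <- function(values, age, sex) {
  if (length(age) != length(values) || length(sex) != length(values))
    stop("covariates must align with values")
  X <- cbind(1, age, sex)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient adjustment design (constant age or sex?)")
  fit <- stats::lm.fit(X, values)
  fit$residuals + mean(values)
}

#' Pointwise group test along a tract profile
#'
#' The node-by-node group comparison at the heart of tract-profile
#' analysis: for every one of the tract's nodes, the chosen one-way test
#' (classic, Welch or Brown-Forsythe) is applied to the per-group node
#' values of tracked subjects, after optional linear age/sex adjustment.
#' By default significance is assessed at raw `alpha` per node (matching
#' common practice in tract-profile studies); Benjamini-Hochberg FDR
#' correction across the nodes is available via `fdr = TRUE`.
#'
#' @param profiles a `tract_profile_set` (long data.frame as produced by
#'   [generate_tract_profiles()] or [read_tract_profiles_csv()]).
#' @param tract tract name.
#' @param metric `"FA"` or `"MD"`.
#' @param test `"anova"`, `"welch"` or `"brown_forsythe"`.
#' @param alpha per-node significance level (default 0.05).
#' @param adjust logical: residualize on age and sex first (requires
#'   `age`/`sex` columns).
#' @param fdr logical: apply Benjamini-Hochberg correction across nodes.
#' @param excluded optional character vector of excluded tracts (e.g. from
#'   [exclude_untrackable_tracts()]); asking for one is an error, not an
#'   empty result.
#' @return data.frame of class `node_test_result`: one row per node with
#'   `node`, `statistic`, `df1`, `df2`, `p`, `significant`; the significant
#'   node set is in attribute `significant_nodes`.
#' @export
pointwise_profile_test <- function(profiles, tract, metric,
                                   test = c("anova", "welch", "brown_forsythe"),
                                   alpha = 0.05, adjust = TRUE, fdr = FALSE,
                                   excluded = NULL) {
  test <- match.arg(test)
  if (!is.null(excluded) && tract %in% excluded)
    stop("tract '", tract, "' is excluded by the tracking-failure rule; ",
         "refusing to test it")
  d <- profiles[profiles$tract == tract & profiles$metric == metric &
                  profiles$tracked == 1L, , drop = FALSE]
  if (nrow(d) == 0L) stop("no tracked data for tract '", tract, "', metric ", metric)
  if (length(unique(d$group)) < 2L)
    stop("need at least two groups among tracked subjects")
  if (adjust && !all(c("age", "sex") %in% names(d)))
    stop("age/sex columns required for covariate adjustment")
  tfun <- switch(test, anova = anova_oneway, welch = welch_anova,
                 brown_forsythe = brown_forsythe)
  nodes <- sort(unique(d$node))
  res <- lapply(nodes, function(nd) {
    dn <- d[d$node == nd, , drop = FALSE]
    vals <- dn$value
    if (adjust) vals <- adjust_covariates(vals, dn$age, dn$sex)
    r <- tfun(split(vals, dn$group))
    data.frame(node = nd, statistic = r$statistic, df1 = r$df1,
               df2 = r$df2, p = r$p.value)
  })
  out <- do.call(rbind, res)
  p_eff <- if (fdr) stats::p.adjust(out$p, method = "BH") else out$p
  out$significant <- p_eff < alpha
  attr(out, "significant_nodes") <- out$node[out$significant]
  attr(out, "tract") <- tract
  attr(out, "metric") <- metric
  attr(out, "test") <- test
  class(out) <- c("node_test_result", "data.frame")
  out
}

#' Post hoc pairwise t-tests at selected nodes
#'
#' Two-sample two-sided t-tests (Welch) on every group pair, on the
#' age/sex-adjusted node values averaged over the requested node range.
#' Typically gated on nodes the overall pointwise test flagged.
#'
#' @inheritParams pointwise_profile_test
#' @param nodes integer vector of node indices (0-based) to average over.
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `statistic`, `df`, `p`.
#' @export
posthoc_pairwise <- function(profiles, tract, metric, nodes, adjust = TRUE) {
  d <- profiles[profiles$tract == tract & profiles$metric == metric &
                  profiles$tracked == 1L & profiles$node %in% nodes, , drop = FALSE]
  if (nrow(d) == 0L) stop("no tracked data in the requested node range")
  agg <- stats::aggregate(value ~ subject_id + group, data = d, FUN = mean)
  if (adjust) {
    demo <- d[!duplicated(d$subject_id), c("subject_id", "age", "sex")]
    agg <- merge(agg, demo, by = "subject_id", sort = FALSE)
    agg$value <- adjust_covariates(agg$value, agg$age, agg$sex)
  }
  gs <- split(agg$value, agg$group)
  pairs <- utils::combn(names(gs), 2L)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    if (length(gs[[g1]]) < 2L || length(gs[[g2]]) < 2L) {
      warning("pair ", g1, " vs ", g2, " skipped: fewer than 2 tracked subjects")
      next
    }
    tt <- stats::t.test(gs[[g1]], gs[[g2]])
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = g1, group2 = g2, statistic = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value)
  }
  do.call(rbind, rows)
}

#' Exclude tracts with too many tracking failures
#'
#' AFQ tractography sometimes cannot identify a tract in a subject; a tract
#' that fails in more than `max_failure_fraction` of subjects is dropped
#' from further analysis.  The default threshold 0.25 drops tracts failing
#' in over a quarter of the cohort while retaining any tract with zero
#' failures.
#'
#' @param profiles a `tract_profile_set`, or a data.frame with columns
#'   `subject_id`, `tract`, `tracked`.
#' @param max_failure_fraction threshold in `[0, 1)`; strictly exceeding it
#'   drops the tract (so 0 drops any tract with at least one failure).
#' @return List: `retained` (character vector), `excluded`, and `report`
#'   (data.frame: tract, n_subjects, n_failed, failure_fraction).
#' @export
exclude_untrackable_tracts <- function(profiles, max_failure_fraction = 0.25) {
  flags <- unique(as.data.frame(profiles)[, c("subject_id", "tract", "tracked")])
  rep_df <- do.call(rbind, lapply(split(flags, flags$tract), function(d)
    data.frame(tract = d$tract[1L], n_subjects = nrow(d),
               n_failed = sum(d$tracked == 0L))))
  rep_df$failure_fraction <- rep_df$n_failed / rep_df$n_subjects
  rep_df <- rep_df[order(-rep_df$failure_fraction, rep_df$tract), ]
  rownames(rep_df) <- NULL
  drop <- rep_df$failure_fraction > max_failure_fraction
  list(retained = sort(rep_df$tract[!drop]),
       excluded = sort(rep_df$tract[drop]),
       report = rep_df)
}
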