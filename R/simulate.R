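#' Simulate one continuous-time Markov path
#'
#' Gillespie-style forward simulation: the holding time in each state is
#' exponential with rate equal to the total exit rate, and the destination
#' is drawn in proportion to the individual transition rates.  A state with
#' zero exit rate (the absorbing AD state, or any state under a zero
#' generator) is never left.
#'
#' Randomness is taken from R's current RNG stream; seed with `set.seed()`
#' (or wrap in `withr::with_seed()`) for reproducibility.
#'
#' @param Q square rate matrix (rows sum to zero, off-diagonals >= 0).
#' @param initial_state state id or label.
#' @param t_max follow-up length in years (`>= 0`).
#' @return data.frame with columns `time` (jump times, starting at 0) and
#'   `state` (state id entered at that time); piecewise-constant path on
#'   `[0, t_max]`.
#' @export
simulate_ctmc_path <- function(Q, initial_state, t_max) {
  validate_rate_matrix(Q)
  if (t_max < 0) stop("t_max must be nonnegative")
  s <- state_index(initial_state)
  times <- 0
  states <- s
  t <- 0
  repeat {
    exit <- -Q[s, s]
    if (exit <= 0) break
    t <- t + stats::rexp(1L, exit)
    if (t > t_max) break
    probs <- Q[s, ]
    probs[s] <- 0
    s <- sample.int(nrow(Q), 1L, prob = probs)
    times <- c(times, t)
    states <- c(states, s)
  }
  data.frame(time = times, state = states)
}

#' Observe a path at visit times
#'
#' Interval censoring: the continuous path is seen only at the scheduled
#' observation times; the jump times themselves are discarded.
#'
#' @param path a path from [simulate_ctmc_path()].
#' @param obs_times sorted nonnegative visit times (years).
#' @return data.frame with columns `time` and `state` (state id at each
#'   visit).
#' @export
sample_panel <- function(path, obs_times) {
  if (is.unsorted(obs_times, strictly = FALSE) || any(obs_times < 0))
    stop("obs_times must be sorted and nonnegative")
  idx <- findInterval(obs_times, path$time)
  idx[idx < 1L] <- 1L
  data.frame(time = obs_times, state = path$state[idx])
}

#' Synthetic-cohort configuration
#'
#' Bundles everything that defines a simulated panel cohort: group sizes,
#' the true generating rates and covariate coefficients, per-group
#' covariate distributions, and the visit schedule.  The defaults emulate a
#' 120-subject memory-clinic discovery cohort: 39 NC, 34 aMCI and 47 AD
#' subjects with near-identical age and sex distributions across groups and
#' strongly group-separated MMSE; annual follow-up (4 visits, gaps uniform
#' on 0.75-1.25 years); annual aMCI-to-AD conversion rate 0.25 (amnestic
#' MCI carries a 20-40% yearly dementia risk), NC-to-aMCI incidence 0.10
#' and aMCI-to-NC reversion 0.10; no covariate effect on the rates unless
#' `true_betas` is set.
#'
#' @param group_sizes named integer vector, subjects per diagnostic group.
#' @param true_rates named vector of generating baseline rates (per year).
#' @param true_betas optional coefficient matrix (transitions x covariates).
#' @param covariate_spec per-covariate list: either
#'   `list(dist = "normal", mean = <per-group>, sd = <per-group>,
#'   lower =, upper =)` or `list(dist = "binary", prob = <per-group>)`;
#'   per-group values are named by group or recycled.
#' @param n_visits number of visits per subject.
#' @param visit_gap length-2 vector, uniform bounds on the inter-visit gap
#'   in years.
#' @param missing_visit_prob probability an intermediate visit is skipped.
#' @param seed mandatory integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(NC = 39L, aMCI = 34L, AD = 47L),
                          true_rates = c("NC->aMCI" = 0.10, "aMCI->NC" = 0.10,
                                         "aMCI->AD" = 0.25),
                          true_betas = NULL,
                          covariate_spec = default_covariate_spec(),
                          n_visits = 4L,
                          visit_gap = c(0.75, 1.25),
                          missing_visit_prob = 0,
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(group_sizes < 0)) stop("group sizes must be nonnegative")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% names(ad_states())))
    stop("group_sizes must be named with state labels")
  if (any(true_rates < 0)) stop("rates must be nonnegative")
  if (any(visit_gap <= 0) || visit_gap[2L] < visit_gap[1L])
    stop("visit_gap must be positive bounds (lo, hi)")
  if (n_visits < 1L) stop("n_visits must be >= 1")
  structure(list(group_sizes = group_sizes, true_rates = true_rates,
                 true_betas = true_betas, covariate_spec = covariate_spec,
                 n_visits = as.integer(n_visits), visit_gap = visit_gap,
                 missing_visit_prob = missing_visit_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default covariate distributions for the synthetic cohort
#'
#' Age and MMSE are normal per group and sex is Bernoulli (male = 1), with
#' group means/sds and male proportions matching a memory-clinic cohort in
#' which age and sex do not differ across groups but MMSE does (NC highest,
#' AD lowest; MMSE truncated to its 0-30 range).
#'
#' @return Named list of covariate specifications.
#' @export
default_covariate_spec <- function() {
  list(
    age = list(dist = "normal",
               mean = c(NC = 68.5, aMCI = 69.5, AD = 69.7),
               sd = c(NC = 7.1, aMCI = 8.8, AD = 9.3)),
    sex = list(dist = "binary",
               prob = c(NC = 18 / 39, aMCI = 13 / 34, AD = 20 / 47)),
    mmse = list(dist = "normal",
                mean = c(NC = 28.5, aMCI = 26.6, AD = 16.1),
                sd = c(NC = 1.4, aMCI = 2.5, AD = 7.3),
                lower = 0, upper = 30)
  )
}

group_param <- function(p, group) {
  if (length(p) == 1L && is.null(names(p))) return(p)
  if (!is.null(names(p)) && group %in% names(p)) return(p[[group]])
  stop("covariate parameter has no value for group ", group)
}

draw_covariate <- function(spec, group, n) {
  if (spec$dist == "normal") {
    x <- stats::rnorm(n, group_param(spec$mean, group), group_param(spec$sd, group))
    if (!is.null(spec$lower)) x <- pmax(x, spec$lower)
    if (!is.null(spec$upper)) x <- pmin(x, spec$upper)
    x
  } else if (spec$dist == "binary") {
    stats::rbinom(n, 1L, group_param(spec$prob, group))
  } else stop("unknown covariate distribution: ", spec$dist)
}

#' Generate a synthetic panel cohort
#'
#' Draws each subject's covariates from the per-group distributions,
#' simulates a latent progression path under the subject's rate matrix
#' Q(V) starting from the subject's group at entry, and records the state
#' only at the subject's visit times.  The generating model is attached as
#' the `truth` attribute so that parameter-recovery tests can compare
#' estimates against it.
#'
#' @param config a [cohort_config()].
#' @return A [panel_dataset()] with a `group` column and attributes
#'   `truth` (the generating [rate_model()]) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (sum(config$group_sizes) == 0L) stop("empty cohort: all group sizes zero")
  covs <- names(config$covariate_spec)
  model <- rate_model(pmax(config$true_rates, 1e-12),
                      beta = config$true_betas,
                      covariates = if (!is.null(config$true_betas)) covs)
  rows <- vector("list", sum(config$group_sizes))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  sid <- 0L
  for (g in names(config$group_sizes)) {
    ng <- config$group_sizes[[g]]
    if (ng == 0L) next
    covmat <- matrix(0, ng, length(covs), dimnames = list(NULL, covs))
    for (v in covs) covmat[, v] <- draw_covariate(config$covariate_spec[[v]], g, ng)
    Q0 <- if (is.null(config$true_betas)) build_rate_matrix(model) else NULL
    for (i in seq_len(ng)) {
      sid <- sid + 1L
      V <- covmat[i, ]
      Q <- if (is.null(Q0)) build_rate_matrix(model, V) else Q0
      gaps <- stats::runif(config$n_visits - 1L,
                           config$visit_gap[1L], config$visit_gap[2L])
      times <- cumsum(c(0, gaps))
      keep <- c(TRUE, stats::runif(config$n_visits - 1L) >= config$missing_visit_prob)
      keep[length(keep)] <- TRUE   # last visit always kept
      times <- times[keep]
      path <- simulate_ctmc_path(Q, g, max(times))
      obs <- sample_panel(path, times)
      rows[[sid]] <- list(id = sid, times = obs$time, states = obs$state,
                          group = g, V = V)
    }
  }
  nv <- vapply(rows, function(r) length(r$times), integer(1))
  out <- data.frame(
    subject_id = rep(sprintf("S%04d", vapply(rows, `[[`, integer(1), "id")), nv),
    time_years = unlist(lapply(rows, `[[`, "times")),
    state = names(ad_states())[unlist(lapply(rows, `[[`, "states"))],
    group = rep(vapply(rows, `[[`, character(1), "group"), nv))
  if (length(covs)) {
    Vmat <- do.call(rbind, lapply(rows, `[[`, "V"))
    for (v in covs) out[[v]] <- rep(Vmat[, v], nv)
  }
  pd <- panel_dataset(out, covariates = covs)
  attr(pd, "truth") <- model
  attr(pd, "config") <- config
  pd
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' The 20-tract automated-fiber-quantification tract set
#'
#' @return Character vector of the 20 standard AFQ tract names.
#' @export
afq_tract_names <- function() {
  c("left thalamic radiation", "right thalamic radiation",
    "left corticospinal", "right corticospinal",
    "left cingulum cingulate", "right cingulum cingulate",
    "left cingulum hippocampus", "right cingulum hippocampus",
    "callosum forceps major", "callosum forceps minor",
    "left IFOF", "right IFOF",
    "left ILF", "right ILF",
    "left SLF", "right SLF",
    "left uncinate", "right uncinate",
    "left arcuate", "right arcuate")
}

#' Tract-profile generator configuration
#'
#' Controls the synthetic tract profiles: per tract and group, a smooth
#' 100-node mean curve for fractional anisotropy (FA, dimensionless in
#' (0,1)) and mean diffusivity (MD, in 1e-3 mm^2/s), i.i.d. Gaussian node
#' noise, and a per-tract, per-group probability that tractography fails
#' for a subject (the tract is then flagged untracked).
#'
#' Defaults: FA group effects (NC > aMCI > AD) concentrated at nodes 40-60
#' of the cingulum cingulate and uncinate tracts; MD group effects
#' (NC < aMCI < AD) at nodes 40-60 of the IFOF and callosum forceps minor;
#' elevated tracking failure only for the left/right cingulum hippocampus
#' (52% and 27%), mirroring the tracts that typically fail in clinical AFQ.
#'
#' @param tract_names character vector of tract identifiers.
#' @param n_nodes nodes per tract profile (default 100).
#' @param fa_effect,md_effect group effect size at the affected nodes, in
#'   the units of the metric (subtracted stepwise per group for FA, added
#'   for MD).
#' @param effect_window integer node range (0-based, inclusive) carrying
#'   the group effect; defaults to the middle fifth of the profile
#'   (nodes 40-60 at 100 nodes).
#' @param fa_tracts,md_tracts tracts carrying the FA/MD group effect.
#' @param noise_sd named vector, residual node sd for FA and MD.
#' @param tracking_failure_probs named vector of per-tract failure
#'   probabilities (tracts not named fail with probability 0).
#' @param seed mandatory integer seed.
#' @return Object of class `profile_config`.
#' @export
profile_config <- function(tract_names = afq_tract_names(),
                           n_nodes = 100L,
                           fa_effect = 0.03,
                           md_effect = 0.03,
                           effect_window = NULL,
                           fa_tracts = c("left cingulum cingulate",
                                         "right cingulum cingulate",
                                         "left uncinate", "right uncinate"),
                           md_tracts = c("left IFOF", "right IFOF",
                                         "callosum forceps minor"),
                           noise_sd = c(FA = 0.05, MD = 0.05),
                           tracking_failure_probs =
                             c("left cingulum hippocampus" = 62 / 120,
                               "right cingulum hippocampus" = 32 / 120),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  if (any(tracking_failure_probs < 0 | tracking_failure_probs > 1))
    stop("tracking failure probabilities must lie in [0, 1]")
  if (any(noise_sd < 0)) stop("noise sd must be nonnegative")
  # default window: the middle fifth of the profile (nodes 40-60 at 100)
  if (is.null(effect_window))
    effect_window <- round(c(0.40, 0.60) * (n_nodes - 1L))
  effect_window <- as.integer(effect_window)
  if (effect_window[1L] < 0L || effect_window[2L] >= n_nodes ||
      effect_window[1L] > effect_window[2L])
    stop("effect_window must be an increasing 0-based range inside the node grid")
  structure(list(tract_names = tract_names, n_nodes = as.integer(n_nodes),
                 fa_effect = fa_effect, md_effect = md_effect,
                 effect_window = as.integer(effect_window),
                 fa_tracts = fa_tracts, md_tracts = md_tracts,
                 noise_sd = noise_sd,
                 tracking_failure_probs = tracking_failure_probs,
                 seed = as.integer(seed)),
            class = "profile_config")
}

# smooth baseline mean curves; x in [0,1]. FA stays well inside (0,1) and
# MD (1e-3 mm^2/s units) stays positive. A small tract-specific phase keeps
# the 20 tracts from being identical.
baseline_curve <- function(metric, tract_id, n_nodes) {
  x <- seq(0, 1, length.out = n_nodes)
  phase <- 0.2 * sin(tract_id)
  if (metric == "FA") 0.45 + 0.08 * sin(pi * x + phase) - 0.05 * (x - 0.5)^2
  else 0.80 + 0.06 * cos(pi * x + phase) + 0.04 * (x - 0.5)^2
}

#' Group mean curve for one tract and metric
#'
#' The deterministic mean profile a subject of a given group is generated
#' around: the smooth tract baseline, plus the stepwise group effect (NC
#' unaffected, aMCI one step, AD two steps; FA decreases and MD increases
#' with severity) inside the configured node window of the affected tracts.
#'
#' @param config a [profile_config()].
#' @param tract tract name.
#' @param metric `"FA"` or `"MD"`.
#' @param group group label (`NC`, `aMCI`, `AD`).
#' @return Numeric vector of length `config$n_nodes`.
#' @export
group_mean_curve <- function(config, tract, metric, group) {
  tid <- match(tract, config$tract_names)
  if (is.na(tid)) stop("unknown tract: ", tract)
  mu <- baseline_curve(metric, tid, config$n_nodes)
  sev <- c(NC = 0, aMCI = 1, AD = 2)[[group]]
  window <- (config$effect_window[1L]:config$effect_window[2L]) + 1L
  if (metric == "FA" && tract %in% config$fa_tracts)
    mu[window] <- mu[window] - sev * config$fa_effect
  if (metric == "MD" && tract %in% config$md_tracts)
    mu[window] <- mu[window] + sev * config$md_effect
  mu
}

#' Generate synthetic tract profiles
#'
#' For every subject and tract, draws FA and MD node arrays as the
#' subject's group mean curve plus i.i.d. Gaussian noise (FA clipped to
#' (0,1), MD to positive values), and a tracking-success flag per the
#' configured failure probabilities.
#'
#' @param config a [profile_config()].
#' @param groups named character vector: `subject_id -> group`.
#' @param demographics optional data.frame with columns `subject_id`,
#'   `age`, `sex` carried into the output (needed for covariate-adjusted
#'   testing downstream).
#' @return Object of class `tract_profile_set`: a long data.frame with
#'   columns `subject_id`, `group`, `tract`, `metric`, `node` (0-based),
#'   `value`, `tracked` plus any demographic columns.
#' @export
generate_tract_profiles <- function(config, groups, demographics = NULL) {
  stopifnot(inherits(config, "profile_config"))
  if (is.null(names(groups))) stop("groups must be named by subject_id")
  bad <- setdiff(unique(groups), names(ad_states()))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  nn <- config$n_nodes
  ids <- names(groups)
  blocks <- vector("list", length(config$tract_names) * 2L)
  bi <- 0L
  for (tract in config$tract_names) {
    pfail <- if (tract %in% names(config$tracking_failure_probs))
      config$tracking_failure_probs[[tract]] else 0
    tracked <- stats::rbinom(length(ids), 1L, 1 - pfail)
    for (metric in c("FA", "MD")) {
      mu <- vapply(c("NC", "aMCI", "AD"), function(g)
        group_mean_curve(config, tract, metric, g), numeric(nn))
      vals <- mu[, groups, drop = FALSE] +
        matrix(stats::rnorm(nn * length(ids), 0, config$noise_sd[[metric]]),
               nn, length(ids))
      if (metric == "FA") vals <- pmin(pmax(vals, 1e-6), 1 - 1e-6)
      else vals <- pmax(vals, 1e-6)
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(
        subject_id = rep(ids, each = nn),
        group = rep(unname(groups), each = nn),
        tract = tract, metric = metric,
        node = rep(0:(nn - 1L), length(ids)),
        value = as.vector(vals),
        tracked = rep(tracked, each = nn))
    }
  }
  out <- do.call(rbind, blocks)
  if (!is.null(demographics)) {
    out <- merge(out, demographics, by = "subject_id", sort = FALSE)
    out <- out[order(match(out$tract, config$tract_names), out$metric,
                     match(out$subject_id, ids), out$node), ]
    rownames(out) <- NULL
  }
  structure(out, n_nodes = nn, class = c("tract_profile_set", "data.frame"))
}

#' Per-group summary table of a panel cohort
#'
#' The demographics/neuropsychology summary a clinical paper prints as its
#' "Table 1": per diagnostic group, the subject count, mean and sd of each
#' continuous covariate, and male/female counts if a binary `sex` covariate
#' is present.
#'
#' @param panel a [panel_dataset()] with a `group` column.
#' @return data.frame with columns `variable`, `group`, `n`, `mean`, `sd`
#'   (for `sex`: `mean` is the male count, `sd` the female count).
#' @export
generate_summary_table <- function(panel) {
  if (nrow(panel) == 0L) stop("empty dataset")
  covs <- attr(panel, "covariates")
  first <- panel[!duplicated(panel$subject_id), , drop = FALSE]
  rows <- list()
  for (v in covs) {
    for (g in unique(first$group)) {
      x <- first[[v]][first$group == g]
      if (v == "sex") {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, group = g, n = length(x),
          mean = sum(x == 1), sd = sum(x == 0))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, group = g, n = length(x),
          mean = mean(x), sd = stats::sd(x))
      }
    }
  }
  do.call(rbind, rows)
}
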