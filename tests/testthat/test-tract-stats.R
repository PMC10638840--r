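test_that("classic ANOVA matches a from-scratch sums-of-squares oracle", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  # direct computation: SSB = 3*((2-3)^2 + 0 + 1) = 6, SSW = 2+2+2 = 6
  # F = (6/2) / (6/6) = 3
  r <- anova_oneway(g)
  expect_equal(r$statistic, 3)
  expect_equal(r$df1, 2); expect_equal(r$df2, 6)
  expect_equal(r$p.value, pf(3, 2, 6, lower.tail = FALSE))
  # cross-check against the standard linear-model route
  set.seed(41)
  for (i in 1:20) {
    gs <- lapply(sample(3:6, 3, TRUE), function(n) rnorm(n))
    mine <- anova_oneway(gs)
    ref <- oneway.test(y ~ g, data = data.frame(
      y = unlist(gs), g = rep(seq_along(gs), lengths(gs))), var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), 0.5)
    f <- anova_oneway(list(a, b))$statistic
    t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-10)
  }
})

test_that("identical constant groups give F = 0, p = 1", {
  r <- anova_oneway(list(rep(2, 5), rep(2, 4), rep(2, 6)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  expect_error(anova_oneway(list(1, c(1, 2))), "at least two values")
})

test_that("summary-statistic ANOVA is an exact identity with the raw-data test", {
  set.seed(43)
  for (i in 1:20) {
    gs <- lapply(sample(5:30, 3, TRUE), function(n) rnorm(n, sd = runif(1, 0.5, 3)))
    a <- anova_oneway(gs)
    b <- anova_from_summaries(lengths(gs), sapply(gs, mean), sapply(gs, sd))
    expect_equal(b$statistic, a$statistic, tolerance = 1e-10)
    expect_equal(b$p.value, a$p.value, tolerance = 1e-10)
  }
  expect_equal(anova_from_summaries(c(5, 5), c(1, 1), c(1, 1))$statistic, 0)
  expect_equal(anova_from_summaries(c(5, 5), c(1, 1), c(1, 1))$p.value, 1)
  expect_error(anova_from_summaries(c(5, 5), c(1, 2), c(1, -1)), "nonnegative")
})

test_that("Welch test matches the standard implementation and its k = 2 identity", {
  set.seed(44)
  for (i in 1:20) {
    gs <- lapply(sample(5:20, 3, TRUE), function(n) rnorm(n, sd = runif(1, 0.5, 4)))
    mine <- welch_anova(gs)
    ref <- oneway.test(y ~ g, data = data.frame(
      y = unlist(gs), g = rep(seq_along(gs), lengths(gs))), var.equal = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df2, unname(ref$parameter[2]), tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  }
  for (i in 1:20) {
    a <- rnorm(7, sd = 1); b <- rnorm(12, 1, sd = 3)
    f <- welch_anova(list(a, b))
    tt <- t.test(a, b)          # Welch two-sample t
    expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p.value, tt$p.value, tolerance = 1e-10)
  }
  eq <- list(c(1, 2, 3), c(1, 2, 3) + 0, c(3, 2, 1))
  expect_equal(welch_anova(eq)$statistic, 0)
  expect_equal(welch_anova(eq)$p.value, 1)
  expect_error(welch_anova(list(rep(1, 3), c(1, 2, 3))), "zero within-group variance")
})

test_that("Brown-Forsythe matches a hand-computed toy and its balanced limit", {
  # toy: groups {0, 2} and {1, 5}; n = (2, 2), N = 4
  # means 1 and 3, grand mean 2, numerator = 2*1 + 2*1 = 4
  # variances 2 and 8, denominator = (1 - 1/2)*2 + (1 - 1/2)*8 = 5
  # S* = 0.8; c = (0.2, 0.8); 1/f = 0.04/1 + 0.64/1 => f = 1/0.68
  r <- brown_forsythe(list(c(0, 2), c(1, 5)))
  expect_equal(r$statistic, 0.8, tolerance = 1e-12)
  expect_equal(r$df2, 1 / 0.68, tolerance = 1e-12)
  expect_equal(r$p.value, pf(0.8, 1, 1 / 0.68, lower.tail = FALSE))
  # balanced design with exactly equal group variances: S* equals classic F
  set.seed(45)
  for (i in 1:10) {
    base <- rnorm(8)
    gs <- lapply(c(0, 1, 3), function(mu) mu + base)
    expect_equal(brown_forsythe(gs)$statistic, anova_oneway(gs)$statistic,
                 tolerance = 1e-10)
  }
  eq <- list(c(1, 2, 3), c(2, 1, 3))
  expect_equal(brown_forsythe(eq)$statistic, 0)
})

test_that("the three tests coincide in the balanced equal-variance limit", {
  # equal group sizes and *exactly* equal group variances; the Welch
  # small-sample correction vanishes as n grows
  n <- 400001L
  base <- scale(rnorm(n))[, 1]
  gs <- list(base, base + 0.01, base + 0.02)
  f <- anova_oneway(gs)$statistic
  w <- welch_anova(gs)$statistic
  b <- brown_forsythe(gs)$statistic
  expect_lt(abs(w - f) / f, 1e-6)
  expect_lt(abs(b - f) / f, 1e-12)
})

test_that("each heteroscedastic test keeps its nominal size where classic ANOVA fails", {
  # negative pairing: the biggest group has the smallest variance, which
  # makes the classic F liberal; Welch and Brown-Forsythe stay calibrated
  set.seed(46)
  reps <- 2000L
  n <- c(40, 20, 10); s <- c(1, 2, 4)
  p <- replicate(reps, {
    gs <- mapply(function(ni, si) rnorm(ni, 0, si), n, s, SIMPLIFY = FALSE)
    c(anova_oneway(gs)$p.value, welch_anova(gs)$p.value,
      brown_forsythe(gs)$p.value)
  })
  rej <- rowMeans(p < 0.05)
  expect_gt(rej[1], 0.08)              # classic ANOVA inflated
  expect_lt(abs(rej[2] - 0.05), 0.015) # Welch near nominal
  expect_lt(rej[3], 0.075)             # Brown-Forsythe mildly liberal at
  expect_gt(rej[3], 0.035)             # this extreme ratio, far below classic
})

test_that("ANOVA p-values rank like a permutation oracle on small instances", {
  set.seed(47)
  n_inst <- 50L
  p_anova <- p_perm <- numeric(n_inst)
  for (i in seq_len(n_inst)) {
    y <- rnorm(15, mean = rep(c(0, runif(1, 0, 1.5), runif(1, 0, 1.5)), each = 5))
    g <- rep(1:3, each = 5)
    p_anova[i] <- anova_oneway(split(y, g))$p.value
    # permutation distribution of the F statistic (independent inline F)
    fstat <- function(yy) {
      ms <- tapply(yy, g, mean); gm <- mean(yy)
      ssb <- sum(5 * (ms - gm)^2)
      ssw <- sum((yy - ms[g])^2)
      (ssb / 2) / (ssw / 12)
    }
    f0 <- fstat(y)
    fp <- replicate(2000, fstat(sample(y)))
    p_perm[i] <- mean(fp >= f0 - 1e-12)
  }
  expect_gt(cor(p_anova, p_perm, method = "spearman"), 0.95)
})

test_that("chi-square independence test reproduces closed forms", {
  r <- chi_square_independence(matrix(c(10, 20, 5, 10), 2))  # proportional rows
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # for df = 2 the survival function is exp(-x/2)
  set.seed(48)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    r <- chi_square_independence(tab)
    expect_equal(r$df1, 2)
    expect_equal(r$p.value, exp(-r$statistic / 2), tolerance = 1e-12)
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)), "margins")
  expect_error(chi_square_independence(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("covariate adjustment residualizes exactly and preserves the grand mean", {
  set.seed(49)
  n <- 200
  age <- rnorm(n, 70, 8); sex <- rbinom(n, 1, 0.5)
  # values independent of the covariates survive nearly unchanged: the OLS
  # fit only absorbs the two chance covariate correlations
  cors <- replicate(20, {
    v <- rnorm(n)
    cor(v, adjust_covariates(v, age, sex))
  })
  expect_gt(mean(cors), 0.99)
  v <- rnorm(n)
  adj <- adjust_covariates(v, age, sex)
  expect_equal(mean(adj), mean(v), tolerance = 1e-10)
  # a perfect linear function of age is adjusted to a constant
  v2 <- 2 * age
  adj2 <- adjust_covariates(v2, age, sex)
  expect_equal(adj2, rep(mean(v2), n), tolerance = 1e-8)
  expect_error(adjust_covariates(v, rep(1, n), rep(0, n)), "rank-deficient")
})

test_that("pointwise testing flags injected effects and calibrates under the null", {
  one_tract <- afq_tract_names()[5]   # left cingulum cingulate (FA effect)
  groups <- setNames(rep(c("NC", "aMCI", "AD"), each = 40),
                     sprintf("P%03d", 1:120))
  demo <- data.frame(subject_id = names(groups),
                     age = rnorm(120, 70, 8), sex = rbinom(120, 1, 0.5))
  # power: 1-sd effect at nodes 40-60, 40 per group
  power_cfg <- function(s) profile_config(
    tract_names = one_tract, fa_effect = 0.05,
    noise_sd = c(FA = 0.05, MD = 0.05),
    tracking_failure_probs = numeric(0), seed = s)
  hits <- sapply(1:30, function(r) {
    tp <- generate_tract_profiles(power_cfg(50 + r), groups, demo)
    res <- pointwise_profile_test(tp, one_tract, "FA")
    mean(res$significant[res$node %in% 40:60])
  })
  cfg <- power_cfg(50)
  expect_gte(mean(hits), 0.8)
  # result has one row per node
  tp <- generate_tract_profiles(cfg, groups, demo)
  res <- pointwise_profile_test(tp, one_tract, "FA")
  expect_equal(nrow(res), 100L)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$statistic >= 0))
  # null calibration on an unaffected tract: ~5% of nodes flagged
  frac <- sapply(1:50, function(r) {
    null_cfg <- profile_config(tract_names = one_tract, fa_effect = 0,
                               tracking_failure_probs = numeric(0),
                               seed = 700 + r)
    tp0 <- generate_tract_profiles(null_cfg, groups, demo)
    mean(pointwise_profile_test(tp0, one_tract, "FA")$significant)
  })
  expect_lt(abs(mean(frac) - 0.05), 0.015)
  # excluded tract is refused, not silently emptied
  expect_error(pointwise_profile_test(tp, one_tract, "FA",
                                      excluded = one_tract), "refusing")
})

test_that("post hoc pairwise t-tests behave symmetrically and detect separation", {
  tract <- afq_tract_names()[5]
  groups <- setNames(rep(c("NC", "AD"), each = 30), sprintf("P%03d", 1:60))
  demo <- data.frame(subject_id = names(groups),
                     age = rnorm(60, 70, 8), sex = rbinom(60, 1, 0.5))
  cfg <- profile_config(tract_names = tract, fa_effect = 0.125,  # 5 sd at 2 steps
                        noise_sd = c(FA = 0.05, MD = 0.05),
                        tracking_failure_probs = numeric(0), seed = 51)
  tp <- generate_tract_profiles(cfg, groups, demo)
  ph <- posthoc_pairwise(tp, tract, "FA", nodes = 45:55)
  expect_lt(ph$p[ph$group1 == "AD" & ph$group2 == "NC"], 1e-6)
  # swapping group order flips the sign, not the p-value
  tp_swapped <- tp
  tp_swapped$group <- ifelse(tp$group == "NC", "AD", "NC")
  ph2 <- posthoc_pairwise(tp_swapped, tract, "FA", nodes = 45:55)
  expect_equal(ph2$statistic, -ph$statistic, tolerance = 1e-10)
  expect_equal(ph2$p, ph$p, tolerance = 1e-10)
})

test_that("pairwise p-values are uniform under the null", {
  tract <- afq_tract_names()[1]
  groups <- setNames(rep(c("NC", "aMCI", "AD"), each = 20), sprintf("P%03d", 1:60))
  demo <- data.frame(subject_id = names(groups),
                     age = rnorm(60, 70, 8), sex = rbinom(60, 1, 0.5))
  pmat <- sapply(seq_len(300), function(r) {
    cfg <- profile_config(tract_names = tract, fa_effect = 0, md_effect = 0,
                          tracking_failure_probs = numeric(0), seed = 5200 + r)
    tp <- generate_tract_profiles(cfg, groups, demo)
    posthoc_pairwise(tp, tract, "FA", nodes = 0:99)$p
  })
  # the three pairs share data within a replicate, so each pair's p-values
  # are tested for uniformity separately across independent replicates
  for (pair in 1:3)
    expect_gt(ks.test(pmat[pair, ], "punif")$p.value, 0.01)
})

test_that("tract exclusion drops only tracts exceeding the failure threshold", {
  subjects <- sprintf("P%03d", 1:120)
  flags <- expand.grid(subject_id = subjects, tract = afq_tract_names(),
                       stringsAsFactors = FALSE)
  flags$tracked <- 1L
  fail_l <- flags$tract == "left cingulum hippocampus" &
    flags$subject_id %in% subjects[1:62]
  fail_r <- flags$tract == "right cingulum hippocampus" &
    flags$subject_id %in% subjects[1:32]
  flags$tracked[fail_l | fail_r] <- 0L
  res <- exclude_untrackable_tracts(flags, max_failure_fraction = 0.25)
  expect_equal(length(res$retained), 18L)
  expect_equal(sort(res$excluded),
               sort(c("left cingulum hippocampus", "right cingulum hippocampus")))
  rep_row <- res$report[res$report$tract == "left cingulum hippocampus", ]
  expect_equal(rep_row$n_failed, 62L)
  # no failures: everything retained
  flags$tracked <- 1L
  expect_equal(length(exclude_untrackable_tracts(flags)$retained), 20L)
  # threshold 0: any failure drops the tract
  flags$tracked[1L] <- 0L
  res0 <- exclude_untrackable_tracts(flags, max_failure_fraction = 0)
  expect_equal(res0$excluded, flags$tract[1L])
})
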