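#' Maximum-likelihood fit of the progression model
#'
#' Maximizes the interval-censored panel log-likelihood over the model
#' parameters.  Internally the baseline rates are log-transformed and the
#' covariate coefficients left unconstrained, so the optimization is an
#' unconstrained smooth problem and positivity of the rates is automatic.
#' Standard errors come from the observed information (numerical Hessian of
#' the negative log-likelihood at the maximum).
#'
#' Rates are initialized from crude occurrence/exposure estimates (observed
#' direct transition counts over total follow-up time, floored at 1e-3 per
#' year) and coefficients at zero, unless `init` is supplied.  If some
#' allowed transition is never observed directly in the data its rate is
#' weakly identified; the optimizer bounds log-rates below and the fit
#' reports such rates at the bound with a warning.
#'
#' @param panel a [panel_dataset()].
#' @param structure a [transition_structure()].
#' @param covariates character vector of covariate columns to enter the
#'   log-linear intensity model (default none).
#' @param init optional [rate_model()] used as starting point.
#' @param control list: `maxit` (default 500), `reltol` on the
#'   log-likelihood (default 1e-9), `grad_tol` gradient-norm target for the
#'   convergence diagnostic (default 1e-6).
#' @return Object of class `msm_fit`: `model` (fitted [rate_model()]),
#'   `loglik`, `se` (per internal parameter: log-rates then coefficients),
#'   `vcov`, `convergence` (list: converged flag, optim code, iterations,
#'   gradient norm, message), `init_loglik`, `n_subjects`, `n_intervals`.
#' @export
fit_msm <- function(panel, structure = transition_structure(),
                    covariates = character(0), init = NULL,
                    control = list()) {
  ctl <- list(maxit = 500L, reltol = 1e-9, grad_tol = 1e-6)
  ctl[names(control)] <- control
  if (!all(covariates %in% (attr(panel, "covariates") %||% character(0))))
    stop("requested covariates not present in the panel dataset")
  iv <- panel_intervals(panel)
  if (length(iv$from) == 0L) stop("panel has no consecutive-visit intervals")
  labs <- transition_labels(structure)
  ntr <- length(labs); ncov <- length(covariates)
  V <- iv$V[, covariates, drop = FALSE]

  # crude initialization: direct transition counts / total follow-up
  if (is.null(init)) {
    states <- names(ad_states())
    counts <- stats::setNames(numeric(ntr), labs)
    for (k in seq_along(iv$from)) {
      lab <- paste0(states[iv$from[k]], "->", states[iv$to[k]])
      if (lab %in% labs) counts[lab] <- counts[lab] + 1
    }
    exposure <- sum(iv$dt)
    never_seen <- labs[counts == 0]
    if (length(never_seen))
      warning("no direct observation of transition(s): ",
              paste(never_seen, collapse = ", "),
              "; the corresponding rate(s) are weakly identified")
    r0_init <- pmax(counts / exposure, 1e-3)
    beta_init <- matrix(0, ntr, ncov, dimnames = list(labs, covariates))
  } else {
    r0_init <- init$r0[labs]
    beta_init <- if (ncov) init$beta[labs, covariates, drop = FALSE]
                 else matrix(0, ntr, 0L)
  }

  theta0 <- c(log(r0_init), as.vector(beta_init))
  nll <- function(theta) {
    Qs <- rate_cube(theta, labs, V, ntr, ncov)
    -panel_loglik_cpp(Qs, iv$from, iv$to, iv$dt, iv$subj)
  }
  ll0 <- -nll(theta0)

  lower <- c(rep(log(1e-8), ntr), rep(-Inf, ntr * ncov))
  opt <- stats::optim(theta0, nll, method = "L-BFGS-B", lower = lower,
                      control = list(maxit = ctl$maxit, factr = ctl$reltol / 1e-15))
  grad <- numeric_gradient(nll, opt$par)
  gnorm <- sqrt(sum(grad^2))
  at_bound <- opt$par[seq_len(ntr)] <= log(1e-8) + 1e-6
  if (any(at_bound))
    warning("rate(s) at the lower bound: ", paste(labs[at_bound], collapse = ", "))
  # relative gradient criterion: the L-BFGS-B stopping rule is on the
  # objective change, so the absolute gradient scales with |loglik|
  converged <- opt$convergence == 0L && gnorm < 1e-4 * max(1, abs(opt$value))
  H <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(theta0))

  r0_hat <- stats::setNames(exp(opt$par[seq_len(ntr)]), labs)
  beta_hat <- matrix(opt$par[-seq_len(ntr)], ntr, ncov,
                     dimnames = list(labs, covariates))
  par_names <- c(paste0("log_r0[", labs, "]"),
                 if (ncov) as.vector(outer(labs, covariates,
                                           function(a, b) paste0("beta[", a, ";", b, "]"))))
  names(se) <- par_names
  fit <- list(model = rate_model(r0_hat, beta = if (ncov) beta_hat else NULL,
                                 covariates = covariates, structure = structure),
              loglik = -opt$value, init_loglik = ll0,
              se = se, vcov = vc,
              convergence = list(converged = converged, optim_code = opt$convergence,
                                 iterations = unname(opt$counts[1L]),
                                 grad_norm = gnorm, message = opt$message %||% ""),
              n_subjects = length(iv$ids), n_intervals = length(iv$from))
  class(fit) <- "msm_fit"
  if (!converged)
    warning("optimizer did not satisfy the convergence criteria; ",
            "inspect $convergence (last iterate returned)")
  fit
}

# n-subject cube of rate matrices from the internal parameter vector
rate_cube <- function(theta, labs, V, ntr, ncov) {
  n <- max(nrow(V), 1L)
  logr <- theta[seq_len(ntr)]
  lam <- matrix(rep(exp(logr), each = n), n, ntr)
  if (ncov > 0L) {
    B <- matrix(theta[-seq_len(ntr)], ntr, ncov)
    lam <- lam * exp(V %*% t(B))
  }
  Qs <- array(0, dim = c(3L, 3L, n))
  states <- names(ad_states())
  for (j in seq_len(ntr)) {
    ft <- strsplit(labs[j], "->", fixed = TRUE)[[1L]]
    Qs[match(ft[1L], states), match(ft[2L], states), ] <- lam[, j]
  }
  for (i in 1:3) Qs[i, i, ] <- -colSums(matrix(Qs[i, , ], 3L))
  Qs
}

numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  f0 <- f(x)
  for (i in seq_along(x)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Multi-state Markov model fit\n")
  cat(sprintf("  %d subjects, %d intervals; log-likelihood %.4f\n",
              x$n_subjects, x$n_intervals, x$loglik))
  est <- c(log(x$model$r0), as.vector(x$model$beta))
  tab <- data.frame(estimate = est, se = unname(x$se))
  rownames(tab) <- names(x$se)
  print(tab)
  cat(sprintf("  converged: %s (grad norm %.2e, %d evaluations)\n",
              x$convergence$converged, x$convergence$grad_norm,
              x$convergence$iterations))
  invisible(x)
}

#' Predict probability of AD onset within a horizon
#'
#' For a subject currently in `state` with covariates `V`, the probability
#' of being in the absorbing AD state after `horizon` years is the
#' (state, AD) entry of `exp(horizon * Q(V))`.  Because AD is absorbing
#' this probability is nondecreasing in the horizon.
#'
#' @param fit an `msm_fit` or a [rate_model()].
#' @param state current state label or id.
#' @param horizon years ahead (scalar or vector, all `>= 0`).
#' @param V covariate vector (required if the model has covariates).
#' @return Numeric vector of onset probabilities, one per horizon.
#' @export
predict_onset <- function(fit, state = "NC", horizon = 5, V = NULL) {
  model <- if (inherits(fit, "msm_fit")) fit$model else fit
  if (any(horizon < 0)) stop("horizon must be nonnegative")
  Q <- build_rate_matrix(model, V)
  i <- state_index(state)
  vapply(horizon, function(h) transition_probability(Q, h)[i, 3L], numeric(1))
}
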