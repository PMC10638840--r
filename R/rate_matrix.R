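#' Proportional-intensity rate-matrix model
#'
#' Parameterizes the transition intensities of the progression model.  Each
#' allowed transition q -> q' carries a baseline rate `r0[q->q']` (events
#' per year) and a coefficient vector `beta[q->q', ]`, one entry per
#' covariate; for a subject with covariate vector V the intensity is
#'
#'   o(q, q'; V) = r0 * exp(beta' V),
#'
#' a log-linear (proportional-intensity) covariate model.  With no
#' covariates the intensity is the constant baseline rate.
#'
#' @param r0 named numeric vector of baseline rates, one per allowed
#'   transition, names `"from->to"`; all strictly positive.
#' @param beta optional numeric matrix of coefficients with one row per
#'   transition (same names/order as `r0`) and one column per covariate.
#'   Omit or pass a 0-column matrix for a covariate-free model.
#' @param covariates character vector of covariate names (column names of
#'   `beta`); defaults to `colnames(beta)`.
#' @param structure a [transition_structure()]; defaults to the structure
#'   implied by the names of `r0`.
#' @return An object of class `rate_model`.
#' @export
#' @examples
#' rate_model(c("NC->aMCI" = 0.10, "aMCI->NC" = 0.10, "aMCI->AD" = 0.25))
rate_model <- function(r0, beta = NULL, covariates = NULL, structure = NULL) {
  if (is.null(names(r0)) || any(!nzchar(names(r0))))
    stop("r0 must be a named vector of 'from->to' rates")
  if (any(!is.finite(r0)) || any(r0 <= 0))
    stop("all baseline rates must be strictly positive")
  if (is.null(structure)) structure <- transition_structure(names(r0))
  labs <- transition_labels(structure)
  if (!setequal(names(r0), labs))
    stop("r0 names do not match the transition structure")
  r0 <- r0[labs]
  if (is.null(beta)) beta <- matrix(0, length(labs), 0L)
  beta <- as.matrix(beta)
  if (nrow(beta) != length(labs))
    stop("beta must have one row per allowed transition")
  rownames(beta) <- labs
  if (is.null(covariates)) covariates <- colnames(beta)
  if (ncol(beta) > 0L && is.null(covariates))
    stop("covariate names required when beta has columns")
  colnames(beta) <- covariates
  structure(list(r0 = r0, beta = beta, covariates = covariates %||% character(0),
                 structure = structure),
            class = "rate_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rate_model <- function(x, ...) {
  cat("Proportional-intensity rate model\n")
  cat("Baseline rates (per year):\n")
  print(x$r0)
  if (ncol(x$beta) > 0L) {
    cat("Log-linear covariate coefficients:\n")
    print(x$beta)
  } else cat("No covariates.\n")
  invisible(x)
}

#' Transition intensity for one transition
#'
#' Evaluates `r0 * exp(beta' V)` for a single allowed transition.  Asking
#' for a disallowed transition is a structural error: its intensity is
#' identically zero by construction, not a quantity of the model.
#'
#' @param model a [rate_model()].
#' @param from,to state labels or ids.
#' @param V covariate vector (named or in `model$covariates` order); may be
#'   omitted for a covariate-free model.
#' @return Intensity in events per year (strictly positive scalar).
#' @export
transition_intensity <- function(model, from, to, V = NULL) {
  lab <- paste0(names(ad_states())[state_index(from)], "->",
                names(ad_states())[state_index(to)])
  if (!lab %in% names(model$r0))
    stop("transition ", lab, " is not in the model's structure")
  lp <- 0
  if (ncol(model$beta) > 0L) {
    V <- covariate_row(V, model$covariates)
    lp <- drop(model$beta[lab, , drop = FALSE] %*% V)
  }
  unname(model$r0[[lab]] * exp(lp))
}

covariate_row <- function(V, covariates) {
  if (length(covariates) == 0L) return(numeric(0))
  if (is.null(V)) stop("covariate vector required")
  V <- unlist(V)
  if (!is.null(names(V)) && all(covariates %in% names(V))) V <- V[covariates]
  if (length(V) != length(covariates))
    stop("covariate vector has length ", length(V), ", expected ", length(covariates))
  as.numeric(V)
}

#' Materialize the rate matrix Q(V)
#'
#' Builds the 3 x 3 generator: allowed off-diagonals are the transition
#' intensities under `V`, disallowed off-diagonals are 0, and each diagonal
#' is minus its row sum, so rows sum to zero; the absorbing AD row is all
#' zeros.
#'
#' @inheritParams transition_intensity
#' @return 3 x 3 rate matrix with state dimnames.
#' @export
#' @examples
#' m <- rate_model(c("NC->aMCI" = 0.2, "aMCI->NC" = 0.1, "aMCI->AD" = 0.3))
#' build_rate_matrix(m)
build_rate_matrix <- function(model, V = NULL) {
  states <- ad_states()
  Q <- matrix(0, 3L, 3L, dimnames = list(names(states), names(states)))
  lp <- rep(0, length(model$r0))
  if (ncol(model$beta) > 0L)
    lp <- drop(model$beta %*% covariate_row(V, model$covariates))
  rates <- model$r0 * exp(lp)
  for (lab in names(model$r0)) {
    ft <- strsplit(lab, "->", fixed = TRUE)[[1L]]
    Q[ft[1L], ft[2L]] <- rates[[lab]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

validate_rate_matrix <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("rate matrix must be square")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be nonnegative")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
    stop("rate matrix rows must sum to zero")
  invisible(Q)
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' The interval transition probabilities of the time-homogeneous chain,
#' computed by scaling-and-squaring matrix exponentiation.  Rows sum to one
#' and `P(0)` is the identity.
#'
#' @param Q square rate matrix (rows sum to zero, off-diagonals >= 0).
#' @param t interval length in years, `t >= 0`.
#' @return Stochastic matrix of the same dimension as `Q`.
#' @export
#' @examples
#' m <- rate_model(c("NC->aMCI" = 0.2, "aMCI->NC" = 0.1, "aMCI->AD" = 0.3))
#' transition_probability(build_rate_matrix(m), 1)
transition_probability <- function(Q, t) {
  validate_rate_matrix(Q)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single nonnegative number of years")
  P <- expm_rate_cpp(Q, t)
  dimnames(P) <- dimnames(Q)
  P
}
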