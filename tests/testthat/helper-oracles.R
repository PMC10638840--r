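# Independent oracles used across the suite. These are written against the
# mathematical definitions, not against the package's own code paths.

# Matrix exponential by the uniformization (randomization) series:
# P(t) = sum_k exp(-lambda t) (lambda t)^k / k! * M^k, M = I + Q/lambda.
# Truncated when the remaining Poisson tail mass is below `tol`.
expm_uniformization <- function(Q, t, tol = 1e-14) {
  m <- nrow(Q)
  if (t == 0) return(diag(m))
  lambda <- max(-diag(Q))
  if (lambda == 0) return(diag(m))
  M <- diag(m) + Q / lambda
  lt <- lambda * t
  P <- matrix(0, m, m)
  Mk <- diag(m)
  w <- exp(-lt)          # Poisson(lt) mass at k = 0
  cum <- w
  k <- 0
  repeat {
    P <- P + w * Mk
    if (1 - cum < tol || k > 10000) break
    k <- k + 1
    Mk <- Mk %*% M
    w <- w * lt / k
    cum <- cum + w
  }
  dimnames(P) <- NULL
  P
}

# the three-rate toy generator used in many checks
toy_Q <- function(a = 0.2, b = 0.1, c = 0.3) {
  matrix(c(-a, a, 0,
           b, -(b + c), c,
           0, 0, 0),
         3, 3, byrow = TRUE,
         dimnames = rep(list(c("NC", "aMCI", "AD")), 2))
}

toy_model <- function(a = 0.2, b = 0.1, c = 0.3) {
  rate_model(c("NC->aMCI" = a, "aMCI->NC" = b, "aMCI->AD" = c))
}

# random valid generator on the default structure
random_Q <- function() {
  toy_Q(stats::runif(1, 0.01, 1), stats::runif(1, 0.01, 1),
        stats::runif(1, 0.01, 1))
}

# a small panel dataset built by hand
manual_panel <- function(states, times, covs = NULL) {
  d <- data.frame(subject_id = "S1", time_years = times, state = states)
  if (!is.null(covs)) d <- cbind(d, covs)
  panel_dataset(d, covariates = names(covs) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
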