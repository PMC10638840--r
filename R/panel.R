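#' Interval-censored panel dataset
#'
#' Wraps per-subject visit records: observation times in years from study
#' entry, the diagnosed state at each visit, and subject-level covariates.
#' The true transition instants are never observed — only the state at each
#' visit — which is exactly the interval censoring the panel likelihood
#' accounts for.
#'
#' @param data data.frame with columns `subject_id`, `time_years`,
#'   `state` (values `NC`, `aMCI`, `AD`) and one column per covariate.
#' @param covariates character vector of covariate column names (possibly
#'   empty).  Covariates are taken as subject-constant: the value at the
#'   first visit is used.
#' @return An object of class `panel_dataset`: the validated data.frame
#'   with a `covariates` attribute.
#' @export
panel_dataset <- function(data, covariates = character(0)) {
  req <- c("subject_id", "time_years", "state")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("panel data lacks column(s): ", paste(missing_cols, collapse = ", "))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariate column(s) not present: ", paste(missing_cov, collapse = ", "))
  bad <- which(!data$state %in% names(ad_states()))
  if (length(bad))
    stop("invalid state label at row ", bad[1L], ": '", data$state[bad[1L]], "'")
  data <- data[order(data$subject_id, data$time_years), , drop = FALSE]
  rownames(data) <- NULL
  idx <- split(seq_len(nrow(data)), data$subject_id)
  for (id in names(idx)) {
    i <- idx[[id]]
    if (any(diff(data$time_years[i]) <= 0))
      stop("observation times not strictly increasing for subject ", id)
    s <- state_index(data$state[i])
    if (any(s[-length(s)] == 3L & s[-1L] != 3L))
      stop("subject ", id, " leaves the absorbing AD state")
  }
  structure(data, covariates = covariates, class = c("panel_dataset", "data.frame"))
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("Panel dataset: %d subjects, %d visits, covariates: %s\n",
              length(unique(x$subject_id)), nrow(x),
              if (length(attr(x, "covariates"))) paste(attr(x, "covariates"), collapse = ", ")
              else "(none)"))
  NextMethod()
}

# One row per consecutive-visit interval plus the per-subject covariate
# matrix; the internal form consumed by the likelihood.
panel_intervals <- function(panel) {
  covs <- attr(panel, "covariates") %||% character(0)
  ord <- order(panel$subject_id, panel$time_years)
  sid <- panel$subject_id[ord]
  st <- state_index(panel$state[ord])
  tm <- panel$time_years[ord]
  ids <- unique(sid)
  k <- match(sid, ids)
  firsts <- !duplicated(k)
  V <- matrix(0, length(ids), length(covs), dimnames = list(NULL, covs))
  for (v in seq_along(covs)) V[, v] <- panel[[covs[v]]][ord][firsts]
  within <- !firsts   # row i pairs with row i-1 of the same subject
  list(ids = ids, V = V,
       from = st[which(within) - 1L], to = st[within],
       dt = tm[within] - tm[which(within) - 1L], subj = k[within])
}

#' Interval-censored panel log-likelihood
#'
#' The log-likelihood of a rate model on panel data: conditioning on each
#' subject's first observed state, every consecutive visit pair
#' contributes `log P[state_i-1, state_i](t_i - t_i-1)` evaluated under the
#' subject's own rate matrix `Q(V)`.  An observed transition that is
#' impossible under the structure (e.g. leaving AD) yields `-Inf` with a
#' warning flagging the data/structure conflict.
#'
#' @param panel a [panel_dataset()].
#' @param model a [rate_model()]; its covariates must be present in the
#'   panel.
#' @return Scalar log-likelihood (0 for an empty dataset).
#' @export
panel_log_likelihood <- function(panel, model) {
  iv <- panel_intervals(panel)
  if (length(iv$from) == 0L) return(0)
  Qs <- array(0, dim = c(3L, 3L, length(iv$ids)))
  for (k in seq_along(iv$ids))
    Qs[, , k] <- build_rate_matrix(model, if (ncol(iv$V)) iv$V[k, ] else NULL)
  ll <- panel_loglik_cpp(Qs, iv$from, iv$to, iv$dt, iv$subj)
  if (is.infinite(ll) && ll < 0)
    warning("an observed transition has probability zero under the structure; ",
            "log-likelihood is -Inf (data/structure conflict)")
  ll
}
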