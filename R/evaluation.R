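#' Confusion matrix
#'
#' Counts of true positives, true negatives, false positives and false
#' negatives for a binary classification task.
#'
#' @param TP,TN,FP,FN nonnegative integer counts (total > 0).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Accuracy, specificity and sensitivity
#'
#' The three headline classification metrics:
#' accuracy `(TP + TN) / (TP + TN + FP + FN)`, specificity
#' `TN / (TN + FP)` and sensitivity `TP / (TP + FN)`.  A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' Some sources print sensitivity with a `TP + FP` denominator, which is
#' precision under another name and inconsistent with counting missed
#' positives as FN; `as_printed = TRUE` reproduces that variant for
#' fidelity experiments, the default is the standard `TP / (TP + FN)`.
#'
#' @param cm a [confusion_matrix()].
#' @param as_printed use the `TP/(TP+FP)` sensitivity variant.
#' @return Named numeric vector `accuracy`, `specificity`, `sensitivity`.
#' @export
#' @examples
#' confusion_metrics(confusion_matrix(TP = 99, TN = 97, FP = 3, FN = 1))
confusion_metrics <- function(cm, as_printed = FALSE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens_den <- if (as_printed) cm$TP + cm$FP else cm$TP + cm$FN
  c(accuracy = safe_div(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN),
    specificity = safe_div(cm$TN, cm$TN + cm$FP),
    sensitivity = safe_div(cm$TP, sens_den))
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold across the unique score values, recording
#' (false-positive rate, true-positive rate) operating points anchored at
#' (0,0) and (1,1).  The AUC is computed by the rank (Mann-Whitney)
#' formula, in which tied scores contribute 1/2 — identical to trapezoidal
#' integration of the curve: 1 means perfect ranking of positives above
#' negatives, 0.5 an uninformative score.
#'
#' @param scores numeric vector (higher = more positive).
#' @param labels binary vector (logical, 0/1, or two-level factor; the
#'   second level / 1 / TRUE is positive).
#' @return Object of class `roc_curve`: `points` (data.frame threshold,
#'   fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- binarize_labels(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  if (length(scores) != length(y)) stop("scores and labels must align")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0L] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

binarize_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) > 2L) stop("labels must be binary")
    as.integer(labels == levels(droplevels(labels))[2L])
  } else if (is.logical(labels)) as.integer(labels)
  else {
    u <- sort(unique(labels))
    if (length(u) > 2L) stop("labels must be binary")
    as.integer(labels == u[length(u)])
  }
}

#' Assemble a multimodal feature table
#'
#' Concatenates per-subject feature blocks from the available modalities
#' into one standardized design matrix for classification:
#' * `mm` — model-derived features: predicted AD-onset probabilities at
#'   1, 2 and 5 years from the subject's first observed state under the
#'   fitted progression model;
#' * `dti` — per-tract mean FA and MD over the tract's nodes (tracked
#'   tracts only, restricted to `retained_tracts` if given);
#' * `smri` — any per-subject volumetric features passed in.
#'
#' Every feature column is z-scored; block provenance is kept in the
#' `blocks` attribute.
#'
#' @param labels named vector: `subject_id -> class label`.
#' @param blocks character subset of `c("mm", "dti", "smri")`.
#' @param fit an `msm_fit` (required for the `mm` block).
#' @param panel the [panel_dataset()] the fit used (for the `mm` block).
#' @param profiles a `tract_profile_set` (for the `dti` block).
#' @param retained_tracts optional tract subset for the `dti` block.
#' @param smri data.frame with `subject_id` plus numeric columns (for the
#'   `smri` block).
#' @param horizons onset-probability horizons (years) for the `mm` block.
#' @return Object of class `feature_table`: list with `x` (matrix, rows =
#'   subjects), `labels` (aligned factor), `blocks` (column -> block map).
#' @export
build_feature_table <- function(labels, blocks = c("mm", "dti"),
                                fit = NULL, panel = NULL, profiles = NULL,
                                retained_tracts = NULL, smri = NULL,
                                horizons = c(1, 2, 5)) {
  blocks <- match.arg(blocks, c("mm", "dti", "smri"), several.ok = TRUE)
  if (is.null(names(labels)) || anyNA(labels)) stop("labels must be named and complete")
  ids <- names(labels)
  feats <- list(); prov <- character(0)
  if ("mm" %in% blocks) {
    if (is.null(fit) || is.null(panel)) stop("mm block needs fit and panel")
    first <- panel[!duplicated(panel$subject_id), , drop = FALSE]
    miss <- setdiff(ids, first$subject_id)
    if (length(miss)) stop("subjects missing from mm block: ",
                           paste(miss, collapse = ", "))
    first <- first[match(ids, first$subject_id), , drop = FALSE]
    covs <- fit$model$covariates
    m <- t(vapply(seq_len(nrow(first)), function(i) {
      V <- if (length(covs)) unlist(first[i, covs]) else NULL
      predict_onset(fit, state = first$state[i], horizon = horizons, V = V)
    }, numeric(length(horizons))))
    colnames(m) <- paste0("mm_onset_", horizons, "y")
    feats[[length(feats) + 1L]] <- m
    prov <- c(prov, rep("mm", ncol(m)))
  }
  if ("dti" %in% blocks) {
    if (is.null(profiles)) stop("dti block needs profiles")
    d <- profiles[profiles$tracked == 1L, , drop = FALSE]
    if (!is.null(retained_tracts)) d <- d[d$tract %in% retained_tracts, , drop = FALSE]
    agg <- stats::aggregate(value ~ subject_id + tract + metric, data = d, FUN = mean)
    agg$col <- paste0("dti_", gsub(" ", "_", agg$tract), "_", agg$metric)
    wide <- stats::reshape(agg[, c("subject_id", "col", "value")],
                           idvar = "subject_id", timevar = "col",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    miss <- setdiff(ids, wide$subject_id)
    if (length(miss)) stop("subjects missing from dti block: ",
                           paste(miss, collapse = ", "))
    wide <- wide[match(ids, wide$subject_id), , drop = FALSE]
    m <- as.matrix(wide[, -1L, drop = FALSE])
    # a tract untracked for some subject leaves NA: impute the column mean
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
    feats[[length(feats) + 1L]] <- m
    prov <- c(prov, rep("dti", ncol(m)))
  }
  if ("smri" %in% blocks) {
    if (is.null(smri)) stop("smri block needs a data.frame")
    miss <- setdiff(ids, smri$subject_id)
    if (length(miss)) stop("subjects missing from smri block: ",
                           paste(miss, collapse = ", "))
    sm <- smri[match(ids, smri$subject_id), setdiff(names(smri), "subject_id"),
               drop = FALSE]
    m <- as.matrix(sm)
    colnames(m) <- paste0("smri_", colnames(m))
    feats[[length(feats) + 1L]] <- m
    prov <- c(prov, rep("smri", ncol(m)))
  }
  x <- do.call(cbind, feats)
  rownames(x) <- ids
  sds <- apply(x, 2L, stats::sd)
  x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  attr(x, "scaled:center") <- NULL; attr(x, "scaled:scale") <- NULL
  structure(list(x = x, labels = factor(unname(labels)),
                 blocks = stats::setNames(prov, colnames(x))),
            class = "feature_table")
}

#' Default classifier: ridge-regularized logistic regression
#'
#' A light, deterministic linear scorer used when no classifier is
#' supplied to [cross_validated_eval()]: logistic regression with a small
#' ridge penalty (glmnet, alpha = 0), returning the predicted positive-
#' class probability.
#'
#' @param x_train,y_train training features / binary labels.
#' @param x_test features to score.
#' @return Numeric scores for `x_test`.
#' @export
ridge_logistic_classifier <- function(x_train, y_train, x_test) {
  y <- binarize_labels(y_train)
  if (ncol(x_train) >= 2L) {
    fit <- glmnet::glmnet(x_train, y, family = "binomial", alpha = 0,
                          lambda = 0.05, standardize = FALSE)
    as.numeric(stats::predict(fit, newx = x_test, type = "response"))
  } else {
    df <- data.frame(y = y, x = x_train[, 1L])
    fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = stats::binomial()))
    as.numeric(stats::predict(fit, newdata = data.frame(x = x_test[, 1L]),
                              type = "response"))
  }
}

#' Cross-validated classification evaluation
#'
#' Stratified k-fold cross-validation: fold membership is drawn per class
#' from a seeded RNG, the classifier is trained on each training split and
#' scores the held-out fold, and all out-of-fold scores are pooled into a
#' single ROC curve and (at score threshold 0.5) confusion matrix.
#' Deterministic given `seed`.
#'
#' With more than two label levels the evaluation is run one-vs-rest per
#' class and a named list is returned.
#'
#' @param features a [build_feature_table()] result, or a list with `x`
#'   and `labels`.
#' @param classifier function `(x_train, y_train, x_test) -> scores`;
#'   default [ridge_logistic_classifier()].
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param threshold score threshold for the confusion matrix.
#' @return List of class `cv_eval`: `roc` (a `roc_curve`), `cm` (a
#'   [confusion_matrix()]), `metrics` (from [confusion_metrics()]),
#'   `scores`, `fold` assignment — or a named list of such, one per class,
#'   in the one-vs-rest case.
#' @export
cross_validated_eval <- function(features, classifier = ridge_logistic_classifier,
                                 folds = 5L, seed = 1L, threshold = 0.5) {
  x <- features$x; labels <- features$labels
  if (folds < 2L) stop("folds must be >= 2")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two classes")
  if (nlevels(labels) > 2L) {
    out <- lapply(levels(labels), function(lv) {
      f2 <- list(x = x, labels = factor(ifelse(labels == lv, lv, "rest"),
                                        levels = c("rest", lv)))
      cross_validated_eval(f2, classifier, folds, seed, threshold)
    })
    names(out) <- levels(labels)
    return(out)
  }
  y <- binarize_labels(labels)
  if (min(table(y)) < folds)
    stop("too few subjects in the minority class for ", folds, " folds")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    scores[!tr] <- classifier(x[tr, , drop = FALSE], y[tr], x[!tr, , drop = FALSE])
  }
  pred <- as.integer(scores >= threshold)
  cm <- confusion_matrix(TP = sum(pred == 1L & y == 1L),
                         TN = sum(pred == 0L & y == 0L),
                         FP = sum(pred == 1L & y == 0L),
                         FN = sum(pred == 0L & y == 1L))
  structure(list(roc = roc_auc(scores, y), cm = cm,
                 metrics = confusion_metrics(cm),
                 scores = scores, fold = fold),
            class = "cv_eval")
}

#' @export
print.cv_eval <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation: AUC = %.3f\n", x$roc$auc))
  print(round(x$metrics, 3))
  invisible(x)
}
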