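#' Temporal train/test split
#'
#' Patients are ordered by first operation date (ties broken by patient id)
#' and the earliest `ceiling(ratio * n)` form the training set — the rest the
#' test set. With the default 2:1 ratio, a 150-patient cohort yields 100
#' training and 50 test patients.
#'
#' @param cohort A `kps_cohort` or a clinical data.frame with `patient_id`
#'   and `operation_date`.
#' @param ratio Training fraction (default 2/3).
#' @return List with `train` and `test` character vectors of patient ids.
#' @export
temporal_split <- function(cohort, ratio = 2 / 3) {
  rec <- if (inherits(cohort, "kps_cohort")) cohort$records else cohort
  if (is.null(rec$operation_date) || any(is.na(rec$operation_date)))
    stop("operation dates are required for the temporal split")
  ord <- order(rec$operation_date, rec$patient_id)
  ids <- rec$patient_id[ord]
  n_train <- ceiling(ratio * length(ids))
  list(train = ids[seq_len(n_train)], test = ids[-seq_len(n_train)])
}

# Stratified fold assignment: positives and negatives are spread separately
# across folds, shuffled by the current RNG state.
stratified_folds <- function(y, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assignment <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    if (length(idx) < folds)
      stop("class ", cls, " has fewer members (", length(idx),
           ") than folds (", folds, "); cannot stratify")
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

# Rank-free AUC by concordant-pair counting (ties count 1/2).
roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels != 1]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

#' Classification metrics at a fixed threshold
#'
#' AUC is the probability that a randomly chosen positive outranks a randomly
#' chosen negative (ties counted one half); the remaining metrics come from
#' the confusion matrix at `threshold`. The positive class is the event
#' KPS < 70. With a single class present, AUC is undefined (`NA` with a
#' warning) but the threshold metrics are still returned.
#'
#' @param labels Binary vector (1 = positive).
#' @param scores Positive-class probabilities or scores.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list: `auc`, `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `threshold`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  y <- as.integer(labels)
  auc <- roc_auc(y, scores)
  if (is.na(auc)) warning("AUC undefined: only one class present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  fp <- sum(pred == 1 & y == 0); tn <- sum(pred == 0 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(auc = auc, accuracy = (tp + tn) / length(y), sensitivity = sens,
       specificity = spec, f1 = f1, threshold = threshold)
}

#' Repeated stratified cross-validation
#'
#' The reference protocol is 10 repetitions of stratified fivefold
#' cross-validation: folds are re-drawn each repeat from `seed + repeat`,
#' every patient appears in exactly one validation fold per repeat, and one
#' metric record is emitted per (repeat, fold) — 50 records in the reference
#' setting.
#'
#' @param builder Function `(X, labels, seed) -> model` implementing
#'   [predict_proba()] (see [nn_builder()], [baseline_builder()]).
#' @param X A `kps_feature_matrix` or numeric matrix.
#' @param labels Labels when `X` is a matrix.
#' @param folds,repeats Protocol dimensions (defaults 5 and 10).
#' @param seed Base seed.
#' @param threshold Classification threshold for the non-AUC metrics.
#' @return A `kps_cv_report`: `records` data.frame (repeat, fold, metrics)
#'   and `fold_predictions` (per record: labels, scores) for ROC averaging.
#' @export
repeated_cv <- function(builder, X, labels = NULL, folds = 5L, repeats = 10L,
                        seed = 1L, threshold = 0.5) {
  if (inherits(X, "kps_feature_matrix")) {
    labels <- X$label
    X <- X$values
  }
  y <- as.integer(labels)
  records <- list()
  preds <- list()
  for (r in seq_len(repeats)) {
    assignment <- stratified_folds(y, folds, seed = seed + r)
    for (k in seq_len(folds)) {
      val <- assignment == k
      model <- builder(X[!val, , drop = FALSE], y[!val],
                       seed = seed + r * 1000L + k)
      s <- predict_proba(model, X[val, , drop = FALSE])
      m <- compute_metrics(y[val], s, threshold = threshold)
      records[[length(records) + 1L]] <-
        data.frame(repeat_ = r, fold = k, auc = m$auc, accuracy = m$accuracy,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   f1 = m$f1, threshold = threshold)
      preds[[length(preds) + 1L]] <- list(labels = y[val], scores = s,
                                          repeat_ = r, fold = k)
    }
  }
  structure(list(records = do.call(rbind, records), fold_predictions = preds,
                 folds = folds, repeats = repeats, seed = seed),
            class = "kps_cv_report")
}

#' @export
print.kps_cv_report <- function(x, ...) {
  cat(sprintf("<kps_cv_report> %d repeats x %d folds\n", x$repeats, x$folds))
  mets <- c("auc", "accuracy", "sensitivity", "specificity", "f1")
  for (m in mets)
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, mean(x$records[[m]]),
                stats::sd(x$records[[m]])))
  invisible(x)
}

# Interpolated TPR of one fold's ROC at given FPR values.
fold_tpr_at <- function(labels, scores, fpr_grid) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tpr <- c(0, cumsum(y == 1) / max(1, sum(y == 1)))
  fpr <- c(0, cumsum(y == 0) / max(1, sum(y == 0)))
  stats::approx(fpr, tpr, xout = fpr_grid, ties = max, rule = 2)$y
}

#' Vertically averaged ROC curve
#'
#' Averages per-fold ROC curves on a fixed grid of false-positive rates
#' (101 points from 0 to 1); endpoints are pinned at (0,0) and (1,1).
#'
#' @param fold_predictions List of `list(labels, scores)` pairs, e.g. the
#'   `fold_predictions` of a `kps_cv_report`.
#' @return Data frame with `fpr`, `tpr_mean`, `tpr_sd`.
#' @export
mean_roc_curve <- function(fold_predictions) {
  if (!length(fold_predictions)) stop("need at least one fold")
  grid <- seq(0, 1, length.out = 101)
  tprs <- vapply(fold_predictions,
                 function(f) fold_tpr_at(f$labels, f$scores, grid),
                 numeric(length(grid)))
  tprs <- matrix(tprs, nrow = length(grid))
  tpr_mean <- rowMeans(tprs)
  tpr_mean[1] <- 0; tpr_mean[length(grid)] <- 1
  data.frame(fpr = grid, tpr_mean = tpr_mean,
             tpr_sd = apply(tprs, 1, stats::sd))
}

#' Paired t-test between two metric series
#'
#' Standard paired-samples t statistic over series aligned by (repeat, fold).
#' Zero-variance differences (including identical series) are degenerate: the
#' t statistic is undefined and the result is flagged as a tie with a
#' warning. The CV folds of one protocol overlap, so the test is reported as
#' descriptive, not strictly valid inference.
#'
#' @param a,b Equal-length numeric vectors (length >= 2), paired.
#' @return List with `t`, `p`, `mean_diff`, `df`, `tie`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("zero-variance differences: paired t statistic undefined (tie)")
    return(list(t = NA_real_, p = NA_real_, mean_diff = mean(d),
                df = length(d) - 1L, tie = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       df = unname(tt$parameter), tie = FALSE)
}
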