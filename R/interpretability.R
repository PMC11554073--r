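#' Grouped permutation feature importance
#'
#' For each expert-defined feature group, all of the group's columns are
#' jointly shuffled with one shared row permutation per round — preserving
#' the within-group correlation structure — and the drop in the performance
#' metric relative to the unpermuted baseline is averaged over rounds. The
#' four MRI groups are `pre_lesion`, `post_lesion`, `pre_mask`, `post_mask`;
#' each clinical parameter is its own group (laterality's one-hot columns
#' stay together). Importances are reported in AUC units by default and may
#' be negative; evaluation on held-out data is recommended.
#'
#' @param model A fitted model implementing [predict_proba()].
#' @param X A `kps_feature_matrix` (its `feature_groups` supply the default
#'   grouping) or a numeric matrix.
#' @param labels Labels when `X` is a matrix.
#' @param groups Named list mapping group name to column names; default: the
#'   matrix's own groups.
#' @param n_permutations Permutation rounds per group (default 30).
#' @param seed Integer seed.
#' @param metric `"auc"` or `"accuracy"`.
#' @return Data frame sorted by descending importance: `group`, `importance`,
#'   `sd` (over rounds), `baseline`.
#' @export
grouped_permutation_importance <- function(model, X, labels = NULL,
                                           groups = NULL,
                                           n_permutations = 30L, seed = 1L,
                                           metric = c("auc", "accuracy")) {
  metric <- match.arg(metric)
  if (inherits(X, "kps_feature_matrix")) {
    labels <- X$label
    if (is.null(groups)) groups <- X$feature_groups
    X <- X$values
  }
  if (is.null(groups)) stop("`groups` required when `X` is a plain matrix")
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1")
  y <- as.integer(labels)
  unknown <- setdiff(unlist(groups), colnames(X))
  if (length(unknown))
    stop("group(s) reference unknown column(s): ",
         paste(unknown, collapse = ", "))

  score <- function(M) {
    s <- predict_proba(model, M)
    if (metric == "auc") roc_auc(y, s) else mean((s >= 0.5) == (y == 1))
  }
  baseline <- score(X)
  set.seed(seed)
  perms <- replicate(n_permutations, sample.int(nrow(X)), simplify = FALSE)
  drops <- matrix(NA_real_, n_permutations, length(groups),
                  dimnames = list(NULL, names(groups)))
  for (k in seq_len(n_permutations)) {
    for (g in names(groups)) {
      cols <- groups[[g]]
      Xp <- X
      Xp[, cols] <- X[perms[[k]], cols, drop = FALSE]
      drops[k, g] <- baseline - score(Xp)
    }
  }
  out <- data.frame(group = names(groups),
                    importance = colMeans(drops),
                    sd = apply(drops, 2, stats::sd),
                    baseline = baseline, row.names = NULL)
  out[order(out$importance, decreasing = TRUE), , drop = FALSE]
}
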