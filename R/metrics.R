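#' Classification and ranking metrics for association prediction
#'
#' Computes threshold-based confusion metrics (accuracy, precision, F1 at
#' the given probability threshold) together with rank-based AUC
#' (Mann-Whitney statistic, ties counted half) and AUPR (step-wise
#' precision-recall integration, i.e. average precision with tied scores
#' grouped).
#'
#' @param scores predicted association probabilities.
#' @param labels 0/1 ground-truth labels; both classes must be present.
#' @param threshold binarisation threshold (default 0.5).
#' @return named list `auc`, `aupr`, `accuracy`, `precision`, `f1`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("score/label length mismatch")
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUC/AUPR undefined: only one class present in labels")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  accuracy <- (tp + tn) / length(labels)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  list(auc = auc_rank(scores, labels),
       aupr = aupr_step(scores, labels),
       accuracy = accuracy, precision = precision, f1 = f1)
}

# Mann-Whitney AUC with midrank tie handling.
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Average precision via step integration of the PR curve; tied scores
# are processed as one block.
aupr_step <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  npos <- sum(y == 1L)
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp_cum <- cumsum(y)[grp_end]
  n_cum <- grp_end
  prec <- tp_cum / n_cum
  rec <- tp_cum / npos
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

# mean/sd aggregation across folds of a metric list-of-lists
aggregate_metrics <- function(fold_metrics) {
  keys <- names(fold_metrics[[1L]])
  vals <- sapply(fold_metrics, function(m) unlist(m[keys]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(keys))
  data.frame(metric = keys,
             mean = rowMeans(vals),
             sd = apply(vals, 1L, stats::sd),
             row.names = NULL)
}
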