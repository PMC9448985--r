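#' Area under the ROC curve via the rank statistic
#'
#' Computes AUC as the normalized Mann-Whitney statistic: with mid-ranks for
#' tied scores, `AUC = (sum of positive ranks - P(P+1)/2) / (P * N)`. This
#' equals the exhaustive count of concordant positive-negative score pairs
#' (ties counted 1/2) divided by `P * N`.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels vector of 0/1 labels, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  pos <- sum(labels == 1L); neg <- sum(labels == 0L)
  if (pos == 0L || neg == 0L) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration of the precision-recall curve over the distinct
#' score thresholds, descending: `AUPR = sum_k (R_k - R_{k-1}) * P_k`
#' (average precision). Samples with tied scores enter as one threshold.
#'
#' @inheritParams auc_rank
#' @return AUPR in `(0, 1]`.
#' @export
aupr_step <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels == 1L)
  if (P == 0L) stop("AUPR needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(s[-length(s)] != s[-1L], TRUE)  # last index of each tie group
  tp <- cumsum(y)[keep]
  n_pred <- seq_along(y)[keep]
  prec <- tp / n_pred
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Thresholded classification metrics
#'
#' Accuracy, recall, precision and F1 at a fixed score cutoff (default 0.5;
#' a score >= cutoff predicts the positive class). F1 is 0 when no positive
#' predictions are made.
#'
#' @inheritParams auc_rank
#' @param cutoff decision threshold on the score.
#' @return named numeric vector `accuracy`, `recall`, `precision`, `f1`.
#' @export
threshold_metrics <- function(scores, labels, cutoff = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  acc <- mean(pred == labels)
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = acc, recall = rec, precision = prec, f1 = f1)
}

# ROC curve points (FPR, TPR) at all distinct thresholds, for plotting/export.
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  keep <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(y)[keep]; fp <- cumsum(1L - y)[keep]
  data.frame(fpr = c(0, fp / max(sum(labels == 0L), 1L)),
             tpr = c(0, tp / max(sum(labels == 1L), 1L)))
}

pr_points <- function(scores, labels) {
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  keep <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(y)[keep]
  n_pred <- seq_along(y)[keep]
  data.frame(recall = tp / sum(labels == 1L), precision = tp / n_pred)
}
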