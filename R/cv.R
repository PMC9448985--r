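#' Stratified k-fold cross-validation of a balanced sample set
#'
#' Splits the sample set into k folds, stratified by label so every fold
#' keeps the positive/negative balance; trains the classifier on k-1 folds
#' and scores the held-out fold. Every sample is scored exactly once as
#' held-out. AUC is computed by the rank statistic ([auc_rank()]), AUPR by
#' step-wise precision-recall integration ([aupr_step()]), and the
#' thresholded metrics (accuracy, recall, F1) at `cutoff`. The summary AUC
#' is the arithmetic mean over folds by default; `pooled = TRUE` instead
#' computes each metric once over all held-out scores.
#'
#' @param samples a `gclda_samples` (or list with `features`, `labels`).
#' @param k number of folds (default 5); each class must have at least k
#'   members.
#' @param seed integer seed for the fold assignment.
#' @param classifier a classifier plugin (default [forest_classifier()]).
#' @param cutoff decision threshold for accuracy/recall/F1 (default 0.5).
#' @param pooled if `TRUE`, report metrics over pooled held-out scores
#'   instead of fold averages.
#' @return object of class `gclda_cv`: `folds` (per-sample fold id),
#'   `fold_metrics` (k x 5 data.frame), `mean_metrics`, `scores` (held-out
#'   score per sample), `roc`, `pr` (pooled curve points), `k`, `seed`,
#'   `pooled`.
#' @export
cross_validate <- function(samples, k = 5, seed = 1,
                           classifier = forest_classifier(),
                           cutoff = 0.5, pooled = FALSE) {
  y <- samples$labels
  stopifnot(k >= 2)
  if (min(table(y)) < k)
    stop(sprintf("k = %d exceeds the size of the smaller class (%d)",
                 k, min(table(y))))
  folds <- make_stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- folds == f
    model <- classifier$fit(list(features = samples$features[tr, , drop = FALSE],
                                 labels = y[tr]),
                            seed = seed + f)
    s <- classifier$score(model, samples$features[te, , drop = FALSE])
    scores[te] <- s
    fold_metrics[[f]] <- c(auc = auc_rank(s, y[te]),
                           aupr = aupr_step(s, y[te]),
                           threshold_metrics(s, y[te], cutoff)[c("recall",
                                                                 "accuracy",
                                                                 "f1")])
  }
  fold_metrics <- as.data.frame(do.call(rbind, fold_metrics))
  mean_metrics <- if (pooled) {
    c(auc = auc_rank(scores, y), aupr = aupr_step(scores, y),
      threshold_metrics(scores, y, cutoff)[c("recall", "accuracy", "f1")])
  } else colMeans(fold_metrics)
  structure(list(folds = folds, fold_metrics = fold_metrics,
                 mean_metrics = mean_metrics, scores = scores, labels = y,
                 roc = roc_points(scores, y), pr = pr_points(scores, y),
                 k = k, seed = seed, pooled = pooled,
                 classifier = classifier$label, cutoff = cutoff),
            class = "gclda_cv")
}

# Stratified fold ids: within each class, shuffle then deal round-robin.
make_stratified_folds <- function(labels, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  folds
}

#' @export
print.gclda_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (%s, %s metrics)\n",
              x$k, x$classifier, if (x$pooled) "pooled" else "fold-averaged"))
  print(round(x$mean_metrics, digits))
  invisible(x)
}

#' @export
summary.gclda_cv <- function(object, ...) {
  cat(sprintf("%d-fold cross-validation, classifier: %s\n",
              object$k, object$classifier))
  cat("\nPer-fold metrics:\n")
  print(round(object$fold_metrics, 4))
  cat("\nSummary metrics:\n")
  print(round(object$mean_metrics, 4))
  invisible(object)
}

#' Plot ROC and precision-recall curves of a cross-validation
#'
#' @param x a `gclda_cv`.
#' @param which `"roc"`, `"pr"`, or `"both"` (default; side by side).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gclda_cv <- function(x, which = c("both", "roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  if (which %in% c("both", "roc")) {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("ROC (AUC = %.4f)", x$mean_metrics[["auc"]]),
                   ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which %in% c("both", "pr")) {
    graphics::plot(x$pr$recall, x$pr$precision, type = "l",
                   xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
                   main = sprintf("PR (AUPR = %.4f)", x$mean_metrics[["aupr"]]),
                   ...)
  }
  invisible(x)
}
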