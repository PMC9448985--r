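#' Random-forest classifier over paired features
#'
#' Trains a classification random forest on a balanced sample set via the
#' ranger engine with the classical defaults: `ntree = 500` trees and
#' `mtry = floor(sqrt(p))` candidate features per split. A pair's score is
#' the fraction of trees voting for the positive class, so it always lies in
#' `[0, 1]`. Training is reproducible under `seed` (single-threaded).
#'
#' @param samples a `gclda_samples` from [build_samples()], or any list with
#'   `features` (matrix) and `labels` (0/1 with both classes present).
#' @param ntree number of trees (default 500).
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param seed integer seed for tree growing.
#' @return object of class `gclda_forest` wrapping the fitted ranger model.
#' @export
train_forest <- function(samples, ntree = 500, mtry = NULL, seed = 1) {
  x <- samples$features; y <- samples$labels
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(unique(y)) < 2L)
    stop("sample set contains a single class")
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (mtry > p) stop(sprintf("mtry (%d) exceeds feature width (%d)", mtry, p))
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(p))
  fit <- ranger::ranger(y = factor(y, levels = c(0L, 1L)), x = df,
                        num.trees = ntree, mtry = mtry,
                        seed = as.integer(seed), num.threads = 1L)
  structure(list(model = fit, ntree = ntree, mtry = mtry, seed = seed, p = p),
            class = "gclda_forest")
}

#' Score pairs with a trained forest
#'
#' @param classifier a `gclda_forest`.
#' @param x feature matrix (N x p, same width as at training).
#' @return numeric vector of vote fractions in `[0, 1]`.
#' @export
forest_score <- function(classifier, x) {
  stopifnot(inherits(classifier, "gclda_forest"), is.matrix(x))
  if (ncol(x) != classifier$p)
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(x), classifier$p))
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  votes <- stats::predict(classifier$model, data = df, predict.all = TRUE,
                          num.threads = 1L)$predictions
  rowMeans(votes == 2L)  # factor level 2 is the positive class
}

#' @export
print.gclda_forest <- function(x, ...) {
  cat(sprintf("<gclda_forest> %d trees, mtry = %d, %d features, OOB error %.4f\n",
              x$ntree, x$mtry, x$p, x$model$prediction.error))
  invisible(x)
}

#' Classifier plugin interface
#'
#' The cross-validation and pipeline functions accept any classifier plugin:
#' a list with a `label`, a `fit(samples, seed)` function returning a model,
#' and a `score(model, x)` function returning scores in `[0, 1]`.
#' `forest_classifier()` builds the random-forest plugin that ships enabled;
#' alternative engines (gradient boosting, support-vector machines, ...) can
#' be supplied through the same interface.
#'
#' @param ntree,mtry forest parameters (see [train_forest()]).
#' @return a classifier plugin list.
#' @export
forest_classifier <- function(ntree = 500, mtry = NULL) {
  list(label = "random forest",
       fit = function(samples, seed) train_forest(samples, ntree = ntree,
                                                  mtry = mtry, seed = seed),
       score = forest_score)
}

#' Rank unconfirmed lncRNA candidates for a disease
#'
#' Scores every lncRNA not yet associated with the given disease
#' (`LD[lnc, disease] == 0`) and returns the `top_n` highest-scoring
#' candidates. Ties are broken deterministically by lncRNA name.
#'
#' @param classifier a `gclda_forest` (or plugin model with a matching
#'   `score_fun`).
#' @param LD lncRNA x disease [bipartite_adjacency()].
#' @param lnc_enc,dis_enc encoded feature matrices, rows named by entity.
#' @param disease disease name (must exist in `LD`'s columns).
#' @param top_n number of candidates to return; capped at the number of
#'   unconfirmed lncRNAs.
#' @param score_fun scoring function `(classifier, x) -> scores`
#'   (default [forest_score()]).
#' @return data.frame with columns `lncRNA`, `disease`, `score`, ordered by
#'   non-increasing score.
#' @export
rank_candidates <- function(classifier, LD, lnc_enc, dis_enc, disease,
                            top_n = 20, score_fun = forest_score) {
  .expect_kinds(LD, "lncRNA", "disease", "LD")
  ld <- unclass_matrix(LD)
  if (!disease %in% colnames(ld))
    stop(sprintf("unknown disease: '%s'", disease))
  cand <- rownames(ld)[ld[, disease] == 0L]
  if (length(cand) == 0L)
    return(data.frame(lncRNA = character(), disease = character(),
                      score = numeric()))
  x <- cbind(lnc_enc[cand, , drop = FALSE],
             dis_enc[rep(disease, length(cand)), , drop = FALSE])
  rownames(x) <- NULL; colnames(x) <- NULL
  s <- score_fun(classifier, x)
  o <- order(-s, cand)
  o <- o[seq_len(min(top_n, length(o)))]
  data.frame(lncRNA = cand[o], disease = disease, score = s[o],
             stringsAsFactors = FALSE)
}
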