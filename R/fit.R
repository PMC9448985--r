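#' Fit the geometric-complement lncRNA-disease association model
#'
#' Runs the full modelling pipeline on a tripartite network: (1) the
#' lncRNA-miRNA and miRNA-disease layers are fused into the lncRNA-disease
#' matrix by the geometric complement ([geometric_complement()],
#' [complement_merge()]); (2) Jaccard and Gaussian interaction profile
#' similarities over lncRNAs and diseases are fused by elementwise maximum
#' ([fuse_max()]); (3) raw per-entity features (complement block followed by
#' similarity block, width l + d) are compressed by one autoencoder per
#' entity kind ([train_autoencoder()]); (4) a balanced sample set
#' ([build_samples()]) trains a random forest ([train_forest()]) that scores
#' lncRNA-disease pairs.
#'
#' @param LD lncRNA x disease [bipartite_adjacency()] of observed
#'   associations.
#' @param LM lncRNA x miRNA layer.
#' @param MD miRNA x disease layer.
#' @param latent_dim autoencoder hidden width, one value for both entity
#'   kinds or a length-2 vector `c(lncRNA, disease)` (default 256).
#' @param lambda_tilde GIP raw bandwidth control (default 1).
#' @param jaccard_denominator `"union"` (default) or `"sum"`; see
#'   [jaccard_similarity()].
#' @param similarity_source `"original"` (default) computes similarities from
#'   the observed LD matrix; `"complemented"` computes them from the merged
#'   `ld_new` (GIP on the real-valued profiles, Jaccard on their support).
#' @param epochs,batch_size,learning_rate autoencoder training settings.
#' @param ntree,mtry random-forest settings (see [train_forest()]).
#' @param seed master seed; sub-seeds for the two autoencoders, negative
#'   sampling and tree growing are derived from it.
#' @param align if `TRUE` (default) the three layers are first passed through
#'   [align_layers()] (union mode).
#' @return an object of class `gclda` with components `comp`
#'   (complemented association), `lfj`, `dsj` (fused similarities),
#'   `encoder_lnc`, `encoder_dis`, `lnc_enc`, `dis_enc` (encoded feature
#'   matrices), `samples`, `forest`, `LD`, `config`, `call`.
#' @examples
#' net <- generate_network(synthetic_config(l = 30, m = 40, d = 25, seed = 1))
#' fit <- gclda_fit(net$LD, net$LM, net$MD, latent_dim = 8, epochs = 30,
#'                  ntree = 50, seed = 1)
#' print(fit)
#' head(predict(fit, disease = colnames(net$LD)[1], top_n = 5))
#' @export
gclda_fit <- function(LD, LM, MD, latent_dim = 256, lambda_tilde = 1,
                      jaccard_denominator = c("union", "sum"),
                      similarity_source = c("original", "complemented"),
                      epochs = 200, batch_size = 32, learning_rate = 1e-3,
                      ntree = 500, mtry = NULL, seed = 1, align = TRUE) {
  jaccard_denominator <- match.arg(jaccard_denominator)
  similarity_source <- match.arg(similarity_source)
  latent_dim <- rep_len(as.integer(latent_dim), 2L)
  cl <- match.call()
  if (align) {
    layers <- align_layers(LD, MD, LM, mode = "union")
    LD <- layers$LD; MD <- layers$MD; LM <- layers$LM
  }

  lmd <- geometric_complement(LM, MD)
  comp <- complement_merge(LD, lmd)

  sims <- .fused_similarities(LD, comp, similarity_source,
                              jaccard_denominator, lambda_tilde)
  feats <- build_raw_features(comp, sims$lfj, sims$dsj)

  encoder_lnc <- train_autoencoder(feats$lnc, latent_dim[1L], epochs,
                                   batch_size, learning_rate,
                                   seed = seed + 11L)
  encoder_dis <- train_autoencoder(feats$dis, latent_dim[2L], epochs,
                                   batch_size, learning_rate,
                                   seed = seed + 23L)
  lnc_enc <- encode(encoder_lnc, feats$lnc)
  dis_enc <- encode(encoder_dis, feats$dis)

  samples <- build_samples(LD, lnc_enc, dis_enc, seed = seed)
  forest <- train_forest(samples, ntree = ntree, mtry = mtry, seed = seed)

  config <- list(latent_dim = latent_dim, lambda_tilde = lambda_tilde,
                 jaccard_denominator = jaccard_denominator,
                 similarity_source = similarity_source, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 ntree = ntree, mtry = forest$mtry, seed = seed)
  structure(list(comp = comp, lfj = sims$lfj, dsj = sims$dsj,
                 raw_features = feats,
                 encoder_lnc = encoder_lnc, encoder_dis = encoder_dis,
                 lnc_enc = lnc_enc, dis_enc = dis_enc,
                 samples = samples, forest = forest,
                 LD = LD, LM = LM, MD = MD,
                 config = config, call = cl),
            class = "gclda")
}

# Fused lncRNA and disease similarities from the chosen source matrix.
.fused_similarities <- function(LD, comp, source, denominator, lambda_tilde) {
  if (source == "original") {
    jl <- jaccard_similarity(LD, "rows", denominator)
    jd <- jaccard_similarity(LD, "columns", denominator)
    gl <- gip_similarity(LD, "rows", lambda_tilde)
    gd <- gip_similarity(LD, "columns", lambda_tilde)
  } else {
    supp <- bipartite_adjacency((comp$ld_new > 0) + 0L,
                                "lncRNA", "disease")
    jl <- jaccard_similarity(supp, "rows", denominator)
    jd <- jaccard_similarity(supp, "columns", denominator)
    gl <- .gip_real(comp$ld_new, lambda_tilde)
    gd <- .gip_real(t(comp$ld_new), lambda_tilde)
  }
  list(lfj = fuse_max(gl, jl), dsj = fuse_max(gd, jd))
}

# GIP kernel on real-valued profile rows (complemented-source mode).
.gip_real <- function(m, lambda_tilde) {
  sq <- rowSums(m^2)
  if (all(sq == 0)) stop("undefined bandwidth: all profiles are zero")
  lambda <- lambda_tilde / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * (m %*% t(m))
  d2[d2 < 0] <- 0
  s <- exp(-lambda * d2)
  diag(s) <- 1
  dimnames(s) <- list(rownames(m), rownames(m))
  similarity_matrix(s, source = "gip", lambda = lambda)
}

#' @export
print.gclda <- function(x, ...) {
  cat("Geometric-complement lncRNA-disease association model\n")
  cat(sprintf("  network: %d lncRNAs, %d miRNAs, %d diseases; %d known associations\n",
              nrow(x$LD), ncol(x$LM), ncol(x$LD), sum(x$LD)))
  cat(sprintf("  features: raw width %d -> latent %d (lncRNA), %d (disease)\n",
              ncol(x$raw_features$lnc), x$config$latent_dim[1L],
              x$config$latent_dim[2L]))
  cat(sprintf("  forest: %d trees, mtry %d, OOB error %.4f\n",
              x$config$ntree, x$config$mtry,
              x$forest$model$prediction.error))
  invisible(x)
}

#' @export
summary.gclda <- function(object, ...) {
  print(object)
  cat(sprintf("  complement: %d unconfirmed cells received evidence > 0 (max %.4f)\n",
              sum(object$comp$lmd > 0 & object$comp$ld == 0),
              max(object$comp$lmd)))
  lh1 <- object$encoder_lnc$loss_history
  lh2 <- object$encoder_dis$loss_history
  cat(sprintf("  autoencoder MSE: lncRNA %.3g -> %.3g, disease %.3g -> %.3g over %d epochs\n",
              lh1[1L], lh1[length(lh1)], lh2[1L], lh2[length(lh2)],
              object$config$epochs))
  cat(sprintf("  training set: %d samples (balanced), seed %d\n",
              length(object$samples$labels), object$config$seed))
  invisible(object)
}

#' Score lncRNA-disease pairs with a fitted model
#'
#' With `disease` set, ranks the unconfirmed candidate lncRNAs for that
#' disease (see [rank_candidates()]). With `pairs` set (a data.frame with
#' columns `lncRNA` and `disease`), returns that data.frame with a `score`
#' column appended. With neither, scores all unconfirmed pairs in the
#' network and returns the global top `top_n`.
#'
#' @param object a fitted `gclda`.
#' @param disease optional disease name.
#' @param pairs optional data.frame of pairs to score.
#' @param top_n number of ranked candidates to return (default 20).
#' @param ... unused.
#' @return a data.frame with columns `lncRNA`, `disease`, `score`.
#' @export
predict.gclda <- function(object, disease = NULL, pairs = NULL, top_n = 20,
                          ...) {
  if (!is.null(pairs)) {
    stopifnot(all(c("lncRNA", "disease") %in% names(pairs)))
    x <- cbind(object$lnc_enc[pairs$lncRNA, , drop = FALSE],
               object$dis_enc[pairs$disease, , drop = FALSE])
    rownames(x) <- NULL; colnames(x) <- NULL
    pairs$score <- forest_score(object$forest, x)
    return(pairs)
  }
  if (!is.null(disease))
    return(rank_candidates(object$forest, object$LD, object$lnc_enc,
                           object$dis_enc, disease, top_n))
  ld <- unclass_matrix(object$LD)
  idx <- which(ld == 0L, arr.ind = TRUE)
  all_pairs <- data.frame(lncRNA = rownames(ld)[idx[, 1L]],
                          disease = colnames(ld)[idx[, 2L]],
                          stringsAsFactors = FALSE)
  scored <- predict(object, pairs = all_pairs)
  o <- order(-scored$score, scored$lncRNA, scored$disease)
  scored[o[seq_len(min(top_n, nrow(scored)))], , drop = FALSE]
}

#' Plot autoencoder training loss of a fitted model
#'
#' @param x a fitted `gclda`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gclda <- function(x, ...) {
  l1 <- x$encoder_lnc$loss_history
  l2 <- x$encoder_dis$loss_history
  graphics::matplot(0:(length(l1) - 1L), cbind(l1, l2), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "Epoch", ylab = "Reconstruction MSE",
                    main = "Autoencoder training loss", ...)
  graphics::legend("topright", c("lncRNA", "disease"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Cross-validate a fitted model
#'
#' Evaluates the model by stratified k-fold cross-validation of its balanced
#' sample set. Two leakage-control options go beyond the default protocol:
#' `per_fold_negatives` re-draws the negative class within every fold
#' instead of fixing one negative sample before splitting, and `strict`
#' additionally rebuilds the complement, similarities, features and
#' autoencoders from the training folds' positives only, so held-out pairs
#' leave no trace in the features they are scored with. The default
#' protocol (one fixed sample set, features from the full LD matrix) leaks
#' test-pair membership into the features — the `leakage` field of the
#' returned report says which protocol produced it.
#'
#' @param fit a fitted `gclda`.
#' @param k number of folds (default 5).
#' @param seed fold-assignment / resampling seed (defaults to the fit seed).
#' @param strict rebuild features per fold from training positives only.
#' @param per_fold_negatives resample negatives within each fold.
#' @param pooled report pooled metrics instead of fold averages.
#' @return a `gclda_cv` report (see [cross_validate()]) with a `leakage`
#'   attribute string.
#' @export
gclda_cv <- function(fit, k = 5, seed = NULL, strict = FALSE,
                     per_fold_negatives = FALSE, pooled = FALSE) {
  stopifnot(inherits(fit, "gclda"))
  if (is.null(seed)) seed <- fit$config$seed
  cfg <- fit$config
  classifier <- forest_classifier(ntree = cfg$ntree, mtry = cfg$mtry)
  if (!strict && !per_fold_negatives) {
    out <- cross_validate(fit$samples, k = k, seed = seed,
                          classifier = classifier, pooled = pooled)
    out$leakage <- "full-matrix features, fixed negative sample"
    return(out)
  }
  out <- .cv_refold(fit, k, seed, strict, classifier, pooled)
  out$leakage <- if (strict)
    "per-fold features and negatives (no test leakage)"
  else "full-matrix features, per-fold negatives"
  out
}

# CV with per-fold negative resampling; strict additionally rebuilds the
# feature pipeline from the training folds' positives.
.cv_refold <- function(fit, k, seed, strict, classifier, pooled) {
  ld <- unclass_matrix(fit$LD)
  pos <- which(ld == 1L)
  zero <- which(ld == 0L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pos_fold <- integer(length(pos))
  pos_fold[sample.int(length(pos))] <- rep_len(seq_len(k), length(pos))
  neg <- sample(zero, length(pos))          # disjoint negatives across folds
  neg_fold <- integer(length(neg))
  neg_fold[sample.int(length(neg))] <- rep_len(seq_len(k), length(neg))

  fold_metrics <- vector("list", k)
  cell_scores <- numeric(2L * length(pos))
  cell_labels <- rep(c(1L, 0L), each = length(pos))
  cell_folds <- c(pos_fold, neg_fold)
  cfg <- fit$config
  for (f in seq_len(k)) {
    if (strict) {
      ld_tr <- ld
      ld_tr[pos[pos_fold == f]] <- 0L
      LD_tr <- bipartite_adjacency(ld_tr, "lncRNA", "disease")
      sub <- gclda_fit(LD_tr, fit$LM, fit$MD,
                       latent_dim = cfg$latent_dim,
                       lambda_tilde = cfg$lambda_tilde,
                       jaccard_denominator = cfg$jaccard_denominator,
                       similarity_source = cfg$similarity_source,
                       epochs = cfg$epochs, batch_size = cfg$batch_size,
                       learning_rate = cfg$learning_rate,
                       ntree = cfg$ntree, seed = seed + f, align = FALSE)
      lnc_enc <- sub$lnc_enc; dis_enc <- sub$dis_enc
    } else {
      lnc_enc <- fit$lnc_enc; dis_enc <- fit$dis_enc
    }
    tr_cells <- c(pos[pos_fold != f], neg[neg_fold != f])
    te_cells <- c(pos[pos_fold == f], neg[neg_fold == f])
    tr_y <- c(rep(1L, sum(pos_fold != f)), rep(0L, sum(neg_fold != f)))
    te_y <- c(rep(1L, sum(pos_fold == f)), rep(0L, sum(neg_fold == f)))
    feat <- function(cells) {
      ij <- arrayInd(cells, dim(ld))
      x <- cbind(lnc_enc[rownames(ld)[ij[, 1L]], , drop = FALSE],
                 dis_enc[colnames(ld)[ij[, 2L]], , drop = FALSE])
      rownames(x) <- NULL; colnames(x) <- NULL
      x
    }
    model <- classifier$fit(list(features = feat(tr_cells), labels = tr_y),
                            seed = seed + f)
    s <- classifier$score(model, feat(te_cells))
    # te_cells and which(cell_folds == f) share the order: positive block
    # first, negative block second, each in cell-index order
    cell_scores[cell_folds == f] <- s
    fold_metrics[[f]] <- c(auc = auc_rank(s, te_y),
                           aupr = aupr_step(s, te_y),
                           threshold_metrics(s, te_y)[c("recall", "accuracy",
                                                        "f1")])
  }
  fold_metrics <- as.data.frame(do.call(rbind, fold_metrics))
  mean_metrics <- if (pooled) {
    c(auc = auc_rank(cell_scores, cell_labels),
      aupr = aupr_step(cell_scores, cell_labels),
      threshold_metrics(cell_scores, cell_labels)[c("recall", "accuracy",
                                                    "f1")])
  } else colMeans(fold_metrics)
  structure(list(folds = cell_folds, fold_metrics = fold_metrics,
                 mean_metrics = mean_metrics, scores = cell_scores,
                 labels = cell_labels,
                 roc = roc_points(cell_scores, cell_labels),
                 pr = pr_points(cell_scores, cell_labels),
                 k = k, seed = seed, pooled = pooled,
                 classifier = classifier$label, cutoff = 0.5),
            class = "gclda_cv")
}
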