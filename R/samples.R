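#' Build a balanced training sample set
#'
#' Every observed association (LD == 1) becomes a positive sample; an equal
#' number of unobserved pairs (LD == 0) is drawn uniformly at random without
#' replacement as negatives, so the set is exactly balanced. Each pair's
#' feature vector is the encoded lncRNA vector followed by the encoded
#' disease vector (width 2 x latent_dim). Sampling is reproducible under
#' `seed`.
#'
#' @param LD lncRNA x disease [bipartite_adjacency()].
#' @param lnc_enc encoded lncRNA features, rows named by lncRNA; must cover
#'   all rows of `LD`.
#' @param dis_enc encoded disease features, rows named by disease.
#' @param seed integer seed for negative sampling.
#' @return object of class `gclda_samples`: `pairs` (data.frame of
#'   lncRNA/disease names and indices), `features` (N x 2p matrix),
#'   `labels` (0/1), `seed`.
#' @export
build_samples <- function(LD, lnc_enc, dis_enc, seed = 1) {
  .expect_kinds(LD, "lncRNA", "disease", "LD")
  ld <- unclass_matrix(LD)
  if (!all(rownames(ld) %in% rownames(lnc_enc)))
    stop("lnc_enc does not cover all lncRNAs in LD")
  if (!all(colnames(ld) %in% rownames(dis_enc)))
    stop("dis_enc does not cover all diseases in LD")

  pos <- which(ld == 1L)
  zero <- which(ld == 0L)
  if (length(zero) < length(pos))
    stop(sprintf("only %d unlabeled pairs available for %d positives",
                 length(zero), length(pos)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  neg <- sort(sample(zero, length(pos)))

  all_idx <- c(pos, neg)
  ij <- arrayInd(all_idx, dim(ld))
  pairs <- data.frame(
    lncRNA = rownames(ld)[ij[, 1L]],
    disease = colnames(ld)[ij[, 2L]],
    lnc_index = ij[, 1L], dis_index = ij[, 2L],
    stringsAsFactors = FALSE)
  labels <- rep(c(1L, 0L), c(length(pos), length(neg)))
  features <- cbind(lnc_enc[pairs$lncRNA, , drop = FALSE],
                    dis_enc[pairs$disease, , drop = FALSE])
  rownames(features) <- NULL
  colnames(features) <- NULL
  structure(list(pairs = pairs, features = features, labels = labels,
                 seed = seed),
            class = "gclda_samples")
}

#' @export
print.gclda_samples <- function(x, ...) {
  cat(sprintf("<gclda_samples> %d samples (%d positive, %d negative), %d features\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
              ncol(x$features)))
  invisible(x)
}
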