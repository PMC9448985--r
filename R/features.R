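#' Assemble raw per-entity feature tables
#'
#' Builds the raw feature vector of every lncRNA and every disease from the
#' complemented association matrix and the fused similarities. The i-th
#' lncRNA feature is the i-th row of `ld_new` (length d) followed by the i-th
#' row of the fused lncRNA similarity (length l); the j-th disease feature is
#' the j-th column of `ld_new` (length l) followed by the j-th column of the
#' fused disease similarity (length d). Both tables therefore have width
#' `l + d` — 652 at the canonical 240 lncRNA x 412 disease scale.
#'
#' @param comp a `complemented_association` from [complement_merge()].
#' @param lfj fused lncRNA similarity (l x l `similarity_matrix`).
#' @param dsj fused disease similarity (d x d `similarity_matrix`).
#' @return list with numeric matrices `lnc` (l x (d + l)) and `dis`
#'   (d x (l + d)), row names the entity names.
#' @export
build_raw_features <- function(comp, lfj, dsj) {
  stopifnot(inherits(comp, "complemented_association"))
  ld_new <- comp$ld_new
  l <- nrow(ld_new); d <- ncol(ld_new)
  if (!identical(dim(lfj), c(l, l)))
    stop(sprintf("lfj must be %d x %d", l, l))
  if (!identical(dim(dsj), c(d, d)))
    stop(sprintf("dsj must be %d x %d", d, d))
  lnc <- cbind(ld_new, unclass(lfj))
  dis <- cbind(t(ld_new), unclass(dsj))
  rownames(lnc) <- rownames(ld_new)
  rownames(dis) <- colnames(ld_new)
  colnames(lnc) <- NULL
  colnames(dis) <- NULL
  list(lnc = lnc, dis = dis)
}
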