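#' Geometric complement of the lncRNA-disease matrix
#'
#' Propagates two-hop evidence through shared miRNAs: for lncRNA i and
#' disease j, the score is the number of miRNAs interacting with both,
#' normalized by the total miRNA-degree of the pair,
#' `LMD[i, j] = (LM[i, ] . MD[, j]) / (||LM[i, ]||_1 + ||MD[, j]||_1)`.
#' The score is bounded in `[0, 0.5]`: the dot product cannot exceed the
#' smaller of the two L1 norms, hence never half their sum. When both the
#' lncRNA and the disease have no miRNA partners the ratio is 0/0 and the
#' score is defined as 0 (no heterogeneous evidence); such cells are counted
#' in a warning.
#'
#' @param LM lncRNA x miRNA [bipartite_adjacency()].
#' @param MD miRNA x disease [bipartite_adjacency()].
#' @return numeric matrix (lncRNA x disease) of potential-association scores
#'   in `[0, 0.5]`.
#' @examples
#' lm <- bipartite_adjacency(
#'   matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE,
#'          dimnames = list(c("L1", "L2"), c("M1", "M2"))), "lncRNA", "miRNA")
#' md <- bipartite_adjacency(
#'   matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE,
#'          dimnames = list(c("M1", "M2"), c("D1", "D2"))), "miRNA", "disease")
#' geometric_complement(lm, md)  # [[0.5, 1/3], [1/3, 0.5]]
#' @export
geometric_complement <- function(LM, MD) {
  .expect_kinds(LM, "lncRNA", "miRNA", "LM")
  .expect_kinds(MD, "miRNA", "disease", "MD")
  lm <- .profiles(LM, "rows")
  md <- .profiles(MD, "rows")
  if (ncol(lm) != nrow(md) || !identical(colnames(lm), rownames(md)))
    stop("miRNA registries of LM and MD do not match")
  num <- lm %*% md
  den <- outer(rowSums(lm), colSums(md), "+")
  zero <- den == 0
  if (any(zero))
    warning(sprintf("%d cell(s) with no miRNA evidence on either side set to 0",
                    sum(zero)))
  den[zero] <- 1
  out <- num / den
  out[zero] <- 0
  out
}

#' Merge observed and complemented associations
#'
#' Combines the observed binary LD matrix with the geometric-complement score
#' matrix by elementwise maximum: `ld_new[i, j] = max(LD[i, j], LMD[i, j])`.
#' Because `LMD <= 0.5 < 1`, observed positives are never altered and
#' `ld_new == 1` exactly where `LD == 1`.
#'
#' @param LD lncRNA x disease [bipartite_adjacency()].
#' @param LMD score matrix from [geometric_complement()], same shape as `LD`.
#' @return an object of class `complemented_association` with elements
#'   `ld_new` (real matrix in `[0, 1]`), `lmd`, and `ld` (the observed input).
#' @export
complement_merge <- function(LD, LMD) {
  .expect_kinds(LD, "lncRNA", "disease", "LD")
  ld <- .profiles(LD, "rows")
  if (!identical(dim(ld), dim(LMD)))
    stop(sprintf("shape mismatch: LD is %dx%d, LMD is %dx%d",
                 nrow(ld), ncol(ld), nrow(LMD), ncol(LMD)))
  if (min(LMD) < 0 || max(LMD) > 0.5 + 1e-12)
    stop("LMD entries must lie in [0, 0.5]")
  ld_new <- pmax(ld, LMD)
  dimnames(ld_new) <- dimnames(ld)
  structure(list(ld_new = ld_new, lmd = LMD, ld = ld),
            class = "complemented_association")
}

#' @export
print.complemented_association <- function(x, ...) {
  cat(sprintf(
    "<complemented_association> %d lncRNAs x %d diseases: %d observed, %d complemented cells > 0\n",
    nrow(x$ld_new), ncol(x$ld_new), sum(x$ld == 1),
    sum(x$lmd > 0 & x$ld == 0)))
  invisible(x)
}
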