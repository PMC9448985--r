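#' Jaccard similarity of interaction profiles
#'
#' Computes the pairwise Jaccard similarity between the binary association
#' profiles of one entity set in the LD matrix: rows for lncRNAs, columns for
#' diseases. For profiles a and b the coefficient is
#' |supp(a) n supp(b)| / |supp(a) u supp(b)|. A pair of all-zero profiles has
#' no evidence either way and is scored 0 rather than NaN. The Dice-like
#' variant that divides by |supp(a)| + |supp(b)| is available via
#' `denominator = "sum"`.
#'
#' @param LD a [bipartite_adjacency()] (any binary layer; conventionally the
#'   lncRNA x disease matrix).
#' @param axis `"rows"` to compare row profiles (lncRNAs), `"columns"` for
#'   column profiles (diseases).
#' @param denominator `"union"` (Jaccard, default) or `"sum"` (Dice-like).
#' @return a `similarity_matrix`: symmetric matrix in `[0, 1]` over the chosen
#'   entity set, with attribute `source = "jaccard"`.
#' @examples
#' m <- matrix(c(1, 1, 0, 1, 1, 0), 2, 3, byrow = TRUE,
#'             dimnames = list(c("L1", "L2"), c("D1", "D2", "D3")))
#' ld <- bipartite_adjacency(m, "lncRNA", "disease")
#' jaccard_similarity(ld, "rows")["L1", "L2"]  # 1/3
#' @export
jaccard_similarity <- function(LD, axis = c("rows", "columns"),
                               denominator = c("union", "sum")) {
  axis <- match.arg(axis)
  denominator <- match.arg(denominator)
  m <- .profiles(LD, axis)
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  den <- outer(sizes, sizes, "+")
  if (denominator == "union") den <- den - inter
  s <- ifelse(den > 0, inter / den, 0)
  similarity_matrix(s, source = "jaccard")
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' The GIP kernel on binary association profiles:
#' `K(i, j) = exp(-lambda * ||p_i - p_j||^2)` with bandwidth
#' `lambda = lambda_tilde / mean_i(||p_i||^2)`, i.e. the raw bandwidth
#' control normalized by the average squared profile norm over the entity
#' set. The kernel is symmetric with unit diagonal. An all-zero matrix leaves
#' the bandwidth undefined and is rejected.
#'
#' @inheritParams jaccard_similarity
#' @param lambda_tilde positive raw bandwidth control (default 1).
#' @return a `similarity_matrix` with attribute `source = "gip"`.
#' @export
gip_similarity <- function(LD, axis = c("rows", "columns"), lambda_tilde = 1) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(lambda_tilde), length(lambda_tilde) == 1L,
            lambda_tilde > 0)
  m <- .profiles(LD, axis)
  sq <- rowSums(m^2)
  if (all(sq == 0))
    stop("undefined bandwidth: all profiles are zero (LD has no associations)")
  lambda <- lambda_tilde / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * (m %*% t(m))
  d2[d2 < 0] <- 0  # numeric guard; exact for binary input
  s <- exp(-lambda * d2)
  diag(s) <- 1
  similarity_matrix(s, source = "gip", lambda = lambda,
                    lambda_tilde = lambda_tilde)
}

#' Fuse two similarity matrices by elementwise maximum
#'
#' Merges a Jaccard and a GIP similarity matrix (or any two similarity
#' matrices over the same registry) by taking the larger value at every cell,
#' yielding the fused lncRNA (LFJ) or disease (DSJ) similarity.
#'
#' @param A,B `similarity_matrix` objects over identical registries.
#' @return a `similarity_matrix` with attribute `source = "fused"`.
#' @export
fuse_max <- function(A, B) {
  stopifnot(inherits(A, "similarity_matrix"), inherits(B, "similarity_matrix"))
  if (!identical(dimnames(A), dimnames(B)))
    stop("similarity matrices have mismatched registries")
  similarity_matrix(pmax(unclass(A), unclass(B)), source = "fused")
}

#' @rdname jaccard_similarity
#' @param values symmetric numeric matrix with entries in `[0, 1]` and
#'   identical row/column names.
#' @param source one of `"jaccard"`, `"gip"`, `"fused"`.
#' @param ... further attributes stored on the object.
#' @export
similarity_matrix <- function(values, source = c("jaccard", "gip", "fused"),
                              ...) {
  source <- match.arg(source)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (!is.null(rownames(values)) &&
      !identical(rownames(values), colnames(values)))
    stop("row and column names must agree")
  if (any(values < -1e-12 | values > 1 + 1e-12))
    stop("similarity entries must lie in [0, 1]")
  if (max(abs(values - t(values))) > 1e-12)
    stop("similarity matrix must be symmetric")
  values[values < 0] <- 0
  values[values > 1] <- 1
  values <- (values + t(values)) / 2
  structure(values, source = source, ...,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, source = %s, mean = %.4f\n",
              nrow(x), ncol(x), attr(x, "source"), mean(x)))
  invisible(x)
}

.profiles <- function(LD, axis) {
  stopifnot(inherits(LD, "bipartite_adjacency"))
  m <- unclass_matrix(LD)
  if (length(m) == 0L) stop("empty adjacency matrix")
  storage.mode(m) <- "double"
  if (axis == "columns") m <- t(m)
  m
}
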