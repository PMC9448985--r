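#' Bipartite binary association matrix
#'
#' Constructs one layer of the tripartite lncRNA--miRNA--disease network: a
#' binary matrix whose rows and columns are named entities of a declared kind.
#' The three layers used throughout the package are the lncRNA x disease
#' matrix (LD), the miRNA x disease matrix (MD) and the lncRNA x miRNA matrix
#' (LM). Row and column names act as the entity registries: they must be
#' unique, non-empty strings, and all downstream indexing is by name.
#'
#' @param values numeric or integer matrix with entries in \{0, 1\}; must have
#'   unique, non-empty row and column names.
#' @param row_kind,col_kind entity kind of the rows / columns, one of
#'   `"lncRNA"`, `"miRNA"`, `"disease"`.
#' @return an object of class `bipartite_adjacency`: the validated integer
#'   matrix with attributes `row_kind` and `col_kind`.
#' @examples
#' m <- matrix(c(1, 0, 0, 0), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("D1", "D2")))
#' ld <- bipartite_adjacency(m, "lncRNA", "disease")
#' sum(ld)
#' @export
bipartite_adjacency <- function(values, row_kind, col_kind) {
  row_kind <- match.arg(row_kind, c("lncRNA", "miRNA", "disease"))
  col_kind <- match.arg(col_kind, c("lncRNA", "miRNA", "disease"))
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (length(values) == 0L) stop("adjacency matrix must be non-empty")
  .check_registry(rownames(values), "row")
  .check_registry(colnames(values), "column")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf("non-binary value %s at row '%s', column '%s'",
                 format(values[bad[1L]]),
                 rownames(values)[i[1L]], colnames(values)[i[2L]]))
  }
  storage.mode(values) <- "integer"
  structure(values, row_kind = row_kind, col_kind = col_kind,
            class = c("bipartite_adjacency", "matrix", "array"))
}

.check_registry <- function(nm, what) {
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
    stop(sprintf("%s names must be present and non-empty", what))
  if (anyDuplicated(nm))
    stop(sprintf("duplicate %s name: '%s'", what, nm[duplicated(nm)][1L]))
  invisible(nm)
}

#' @export
print.bipartite_adjacency <- function(x, ...) {
  cat(sprintf("<bipartite_adjacency> %d %s x %d %s, %d associations (density %.4f)\n",
              nrow(x), attr(x, "row_kind"), ncol(x), attr(x, "col_kind"),
              sum(x), mean(x)))
  invisible(x)
}

# Strip class/attrs for plain matrix algebra.
unclass_matrix <- function(x) {
  y <- as.matrix(x)
  attr(y, "row_kind") <- NULL
  attr(y, "col_kind") <- NULL
  class(y) <- NULL
  y
}

#' Read an association layer from a delimited file
#'
#' Two dialects are supported. `format = "dense"`: a labeled dense matrix with
#' a header row of column names and a first column of row names, cells in
#' \{0, 1\}. `format = "edge-list"`: two or three columns
#' `(row_name, col_name[, value])`; a missing value column implies 1, and
#' duplicate edges collapse to a single association. Comma or tab separation
#' is autodetected from the first line.
#'
#' @param path file to read.
#' @param format `"dense"` or `"edge-list"`.
#' @param row_kind,col_kind entity kinds (see [bipartite_adjacency()]).
#' @param row_names,col_names optional explicit registries for edge lists;
#'   otherwise entities are registered in first-appearance order.
#' @param header for edge lists, whether the first line is a header
#'   (default `FALSE`; dense files always carry a header).
#' @return a [bipartite_adjacency()].
#' @export
read_adjacency <- function(path, format = c("dense", "edge-list"),
                           row_kind, col_kind,
                           row_names = NULL, col_names = NULL,
                           header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("empty file: %s", path))
  sep <- if (grepl("\t", first)) "\t" else ","

  if (format == "dense") {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) == 0L) stop(sprintf("empty file: %s", path))
    return(bipartite_adjacency(as.matrix(df), row_kind, col_kind))
  }

  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L && is.null(row_names))
    stop("edge list has no rows and no explicit registries were supplied")
  if (!ncol(df) %in% c(2L, 3L) && nrow(df) > 0L)
    stop("edge list must have 2 or 3 columns")
  rn <- if (is.null(row_names)) unique(as.character(df[[1L]])) else row_names
  cn <- if (is.null(col_names)) unique(as.character(df[[2L]])) else col_names
  .check_registry(rn, "row")
  .check_registry(cn, "column")
  m <- matrix(0L, length(rn), length(cn), dimnames = list(rn, cn))
  if (nrow(df) > 0L) {
    v <- if (ncol(df) >= 3L) df[[3L]] else rep(1, nrow(df))
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary value %s for edge ('%s', '%s')",
                   format(v[bad[1L]]), df[bad[1L], 1L], df[bad[1L], 2L]))
    ri <- match(as.character(df[[1L]]), rn)
    ci <- match(as.character(df[[2L]]), cn)
    if (anyNA(ri) || anyNA(ci))
      stop("edge references an entity absent from the supplied registry")
    keep <- v == 1
    m[cbind(ri[keep], ci[keep])] <- 1L  # duplicates collapse
  }
  bipartite_adjacency(m, row_kind, col_kind)
}

#' Write an association layer to a delimited file
#'
#' Inverse of [read_adjacency()]: round-tripping either format reproduces the
#' matrix exactly. Edge-list output contains one `(row, col)` line per
#' association; an all-zero matrix yields a file with no data rows.
#'
#' @param adj a [bipartite_adjacency()].
#' @param path output file.
#' @param format `"dense"` or `"edge-list"`.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path, format = c("dense", "edge-list"),
                            sep = ",") {
  format <- match.arg(format)
  stopifnot(inherits(adj, "bipartite_adjacency"))
  m <- unclass_matrix(adj)
  if (format == "dense") {
    df <- data.frame(name = rownames(m), m, check.names = FALSE)
    names(df)[1L] <- ""
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(m == 1L, arr.ind = TRUE)
    df <- data.frame(row = rownames(m)[idx[, 1L]],
                     col = colnames(m)[idx[, 2L]])
    df <- df[order(df$row, df$col), , drop = FALSE]
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Align the three network layers onto shared entity registries
#'
#' Re-indexes LD, MD and LM so that each entity set (lncRNA, miRNA, disease)
#' is identical across the layers that use it, making the matrix product
#' LM %*% MD dimensionally coherent with LD. Under `mode = "union"` (default)
#' each layer is padded with zero rows/columns for entities it lacks; under
#' `mode = "intersection"` entities absent from any layer are dropped (an
#' empty intersection is an error).
#'
#' @param LD lncRNA x disease layer.
#' @param MD miRNA x disease layer.
#' @param LM lncRNA x miRNA layer.
#' @param mode `"union"` or `"intersection"`.
#' @return a list with elements `LD`, `MD`, `LM` on shared registries.
#' @export
align_layers <- function(LD, MD, LM, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  .expect_kinds(LD, "lncRNA", "disease", "LD")
  .expect_kinds(MD, "miRNA", "disease", "MD")
  .expect_kinds(LM, "lncRNA", "miRNA", "LM")
  comb <- if (mode == "union") union else intersect
  lnc <- comb(rownames(LD), rownames(LM))
  mir <- comb(colnames(LM), rownames(MD))
  dis <- comb(colnames(LD), colnames(MD))
  for (nm in list(c("lncRNA", length(lnc)), c("miRNA", length(mir)),
                  c("disease", length(dis))))
    if (as.integer(nm[2L]) == 0L)
      stop(sprintf("alignment leaves an empty %s registry", nm[1L]))
  list(LD = .reindex(LD, lnc, dis),
       MD = .reindex(MD, mir, dis),
       LM = .reindex(LM, lnc, mir))
}

.expect_kinds <- function(adj, rk, ck, label) {
  stopifnot(inherits(adj, "bipartite_adjacency"))
  if (!identical(attr(adj, "row_kind"), rk) ||
      !identical(attr(adj, "col_kind"), ck))
    stop(sprintf("%s must be %s x %s, got %s x %s", label, rk, ck,
                 attr(adj, "row_kind"), attr(adj, "col_kind")))
}

.reindex <- function(adj, rn, cn) {
  m <- unclass_matrix(adj)
  out <- matrix(0L, length(rn), length(cn), dimnames = list(rn, cn))
  ri <- intersect(rn, rownames(m))
  ci <- intersect(cn, colnames(m))
  out[ri, ci] <- m[ri, ci]
  bipartite_adjacency(out, attr(adj, "row_kind"), attr(adj, "col_kind"))
}
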