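# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use scalar per-pair loops so they share no code path with the
# vectorized implementations they check.

named_matrix <- function(v, nr, nc, rk = "L", ck = "D", byrow = TRUE) {
  m <- matrix(v, nr, nc, byrow = byrow,
              dimnames = list(paste0(rk, seq_len(nr)),
                              paste0(ck, seq_len(nc))))
  m
}

# Bare numeric values of a similarity/adjacency object (drops class and
# bookkeeping attributes) for comparison against plain-matrix oracles.
sim_values <- function(s) {
  m <- unclass(s)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

adj <- function(v, nr, nc, row_kind = "lncRNA", col_kind = "disease",
                rk = "L", ck = "D") {
  bipartite_adjacency(named_matrix(v, nr, nc, rk, ck), row_kind, col_kind)
}

random_adjacency <- function(nr, nc, p = 0.4, row_kind = "lncRNA",
                             col_kind = "disease", rk = "L", ck = "D") {
  v <- as.integer(stats::runif(nr * nc) < p)
  bipartite_adjacency(named_matrix(v, nr, nc, rk, ck, byrow = FALSE),
                      row_kind, col_kind)
}

# Jaccard over row profiles, one scalar pair at a time.
oracle_jaccard_rows <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    inter <- 0; uni <- 0
    for (k in seq_len(ncol(m))) {
      if (m[i, k] == 1 && m[j, k] == 1) inter <- inter + 1
      if (m[i, k] == 1 || m[j, k] == 1) uni <- uni + 1
    }
    out[i, j] <- if (uni > 0) inter / uni else 0
  }
  out
}

# GIP kernel over row profiles, scalar loops throughout.
oracle_gip_rows <- function(m, lambda_tilde = 1) {
  n <- nrow(m)
  norms2 <- numeric(n)
  for (i in seq_len(n)) norms2[i] <- sum(m[i, ]^2)
  lambda <- lambda_tilde / (sum(norms2) / n)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d2 <- 0
    for (k in seq_len(ncol(m))) d2 <- d2 + (m[i, k] - m[j, k])^2
    out[i, j] <- exp(-lambda * d2)
  }
  diag(out) <- 1
  out
}

# Geometric complement, triple loop.
oracle_complement <- function(lm, md) {
  l <- nrow(lm); d <- ncol(md)
  out <- matrix(0, l, d)
  for (i in seq_len(l)) for (j in seq_len(d)) {
    num <- 0
    for (k in seq_len(ncol(lm))) num <- num + lm[i, k] * md[k, j]
    den <- sum(lm[i, ]) + sum(md[, j])
    out[i, j] <- if (den > 0) num / den else 0
  }
  out
}

# AUC by exhaustive concordant positive-negative pair counting (ties 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (if (p > n) 1 else if (p == n) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# Small planted network used by several predictor tests.
small_planted_network <- function(seed = 1, holdout = 0.15) {
  generate_network(synthetic_config(l = 40, m = 60, d = 30, rank = 3,
                                    ld_density = 0.08, lm_density = 0.12,
                                    md_density = 0.12,
                                    holdout_fraction = holdout, seed = seed))
}

small_fit <- function(net, seed = 1, latent_dim = 12, epochs = 40,
                      ntree = 150, ...) {
  suppressWarnings(gclda_fit(net$LD, net$LM, net$MD, latent_dim = latent_dim,
                             epochs = epochs, ntree = ntree, seed = seed,
                             ...))
}
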