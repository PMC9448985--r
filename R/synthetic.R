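#' Configuration for the planted-structure network generator
#'
#' Defaults emulate the canonical data scale used throughout the package:
#' 240 lncRNAs, 495 miRNAs, 412 diseases, with an LD density of
#' 2697 / (240 * 412) (about 2.73% of pairs observed). The auxiliary layers
#' default to a density of 3%, the same order of sparsity, as typical for
#' curated interactomes. The three layers share non-negative latent factors
#' of the given rank, which is what makes held-out associations recoverable
#' from the remaining evidence.
#'
#' @param l,m,d entity counts (lncRNA, miRNA, disease).
#' @param rank planted latent dimension (default 6).
#' @param ld_density,lm_density,md_density target fraction of ones per layer.
#' @param noise_flip_rate fraction of entries flipped at random after
#'   thresholding (default 0).
#' @param holdout_fraction fraction of LD ones removed into the truth set
#'   (default 0).
#' @param seed integer seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(l = 240, m = 495, d = 412, rank = 6,
                             ld_density = 2697 / (240 * 412),
                             lm_density = 0.03, md_density = 0.03,
                             noise_flip_rate = 0, holdout_fraction = 0,
                             seed = 1) {
  stopifnot(l >= 2, m >= 2, d >= 2, rank >= 1,
            rank <= min(l, m, d),
            ld_density > 0, ld_density < 1,
            lm_density > 0, lm_density < 1,
            md_density > 0, md_density < 1,
            noise_flip_rate >= 0, noise_flip_rate < 1,
            holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(l = l, m = m, d = d, rank = rank,
                 ld_density = ld_density, lm_density = lm_density,
                 md_density = md_density, noise_flip_rate = noise_flip_rate,
                 holdout_fraction = holdout_fraction, seed = seed),
            class = "synthetic_config")
}

#' Generate a tripartite network with planted shared structure
#'
#' Draws non-negative latent factors U (l x rank), V (m x rank), W (d x rank)
#' from a gamma distribution, forms the propensity products U W' (LD),
#' U V' (LM) and V W' (MD), and binarizes each by the quantile threshold
#' that hits the layer's target density. Optionally flips a fraction of
#' entries as noise and removes a fraction of LD ones into a held-out truth
#' set (they stay eligible as prediction candidates, mirroring how novel
#' associations are discovered). Reproducible under the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with [bipartite_adjacency()] layers `LD`, `MD`, `LM`, a
#'   data.frame `truth` of held-out positive pairs, and the `config`.
#' @examples
#' net <- generate_network(synthetic_config(l = 20, m = 30, d = 15, seed = 7))
#' dim(net$LD)
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(cfg$seed))

  U <- matrix(stats::rgamma(cfg$l * cfg$rank, shape = 2, rate = 2),
              cfg$l, cfg$rank)
  V <- matrix(stats::rgamma(cfg$m * cfg$rank, shape = 2, rate = 2),
              cfg$m, cfg$rank)
  W <- matrix(stats::rgamma(cfg$d * cfg$rank, shape = 2, rate = 2),
              cfg$d, cfg$rank)

  binarize <- function(score, density) {
    thr <- stats::quantile(score, probs = 1 - density, names = FALSE)
    out <- (score > thr) + 0L
    if (sum(out) == 0L) stop("density unreachable: no entry above threshold")
    out
  }
  flip <- function(mat, rate) {
    if (rate <= 0) return(mat)
    n_flip <- round(rate * length(mat))
    idx <- sample.int(length(mat), n_flip)
    mat[idx] <- 1L - mat[idx]
    mat
  }
  ld <- flip(binarize(U %*% t(W), cfg$ld_density), cfg$noise_flip_rate)
  lm <- flip(binarize(U %*% t(V), cfg$lm_density), cfg$noise_flip_rate)
  md <- flip(binarize(V %*% t(W), cfg$md_density), cfg$noise_flip_rate)

  dimnames(ld) <- list(sprintf("L%03d", seq_len(cfg$l)),
                       sprintf("D%03d", seq_len(cfg$d)))
  dimnames(lm) <- list(rownames(ld), sprintf("M%03d", seq_len(cfg$m)))
  dimnames(md) <- list(colnames(lm), colnames(ld))

  truth <- data.frame(lncRNA = character(), disease = character(),
                      stringsAsFactors = FALSE)
  if (cfg$holdout_fraction > 0) {
    ones <- which(ld == 1L)
    held <- sample(ones, round(cfg$holdout_fraction * length(ones)))
    ij <- arrayInd(held, dim(ld))
    truth <- data.frame(lncRNA = rownames(ld)[ij[, 1L]],
                        disease = colnames(ld)[ij[, 2L]],
                        stringsAsFactors = FALSE)
    ld[held] <- 0L
  }

  list(LD = bipartite_adjacency(ld, "lncRNA", "disease"),
       MD = bipartite_adjacency(md, "miRNA", "disease"),
       LM = bipartite_adjacency(lm, "lncRNA", "miRNA"),
       truth = truth, config = cfg)
}

#' Write the hand-checkable fixture suite
#'
#' Materializes the small worked examples used across the package (the 2x3
#' Jaccard/GIP rows, the 2x2 geometric-complement case) plus a 12x10x8
#' planted network, each with its expected-output file. Regeneration is
#' byte-identical (fixed seed), so the suite can serve as a regression
#' anchor.
#'
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
make_fixture_suite <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)

  jm <- matrix(c(1L, 0L, 1L, 1L, 1L, 0L), 2, 3, byrow = TRUE,
               dimnames = list(c("L1", "L2"), c("D1", "D2", "D3")))
  write_adjacency(bipartite_adjacency(jm, "lncRNA", "disease"),
                  fp("jaccard_rows.csv"), "dense")
  writeLines(format(1 / 3, digits = 17), fp("jaccard_rows.expected.txt"))
  writeLines(format(exp(-1), digits = 17), fp("gip_rows.expected.txt"))

  lm2 <- matrix(c(1L, 1L, 0L, 1L), 2, 2, byrow = TRUE,
                dimnames = list(c("L1", "L2"), c("M1", "M2")))
  md2 <- matrix(c(1L, 0L, 1L, 1L), 2, 2, byrow = TRUE,
                dimnames = list(c("M1", "M2"), c("D1", "D2")))
  write_adjacency(bipartite_adjacency(lm2, "lncRNA", "miRNA"),
                  fp("lmd_2x2_lm.csv"), "dense")
  write_adjacency(bipartite_adjacency(md2, "miRNA", "disease"),
                  fp("lmd_2x2_md.csv"), "dense")
  expected <- matrix(c(0.5, 1 / 3, 1 / 3, 0.5), 2, 2, byrow = TRUE)
  utils::write.table(format(expected, digits = 17), fp("lmd_2x2.expected.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  net <- generate_network(synthetic_config(l = 12, m = 10, d = 8, rank = 3,
                                           ld_density = 0.2,
                                           lm_density = 0.25,
                                           md_density = 0.25, seed = 42))
  write_adjacency(net$LD, fp("planted_ld.csv"), "dense")
  write_adjacency(net$LM, fp("planted_lm.csv"), "dense")
  write_adjacency(net$MD, fp("planted_md.csv"), "dense")
  invisible(dir)
}
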