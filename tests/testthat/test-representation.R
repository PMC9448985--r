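toy_comp <- function(l = 4, d = 5, seed = 9) {
  set.seed(seed)
  ld <- random_adjacency(l, d, p = 0.4)
  lm <- random_adjacency(l, 3, p = 0.5, col_kind = "miRNA", ck = "M")
  md <- random_adjacency(3, d, p = 0.5, row_kind = "miRNA", rk = "M")
  comp <- complement_merge(ld, suppressWarnings(geometric_complement(lm, md)))
  list(comp = comp,
       lfj = fuse_max(gip_similarity(ld, "rows"),
                      jaccard_similarity(ld, "rows")),
       dsj = fuse_max(gip_similarity(ld, "columns"),
                      jaccard_similarity(ld, "columns")))
}

test_that("raw feature tables concatenate complement and similarity blocks", {
  t <- toy_comp(l = 2, d = 3, seed = 5)
  f <- build_raw_features(t$comp, t$lfj, t$dsj)
  expect_equal(dim(f$lnc), c(2, 5))   # width d + l
  expect_equal(dim(f$dis), c(3, 5))   # width l + d
  expect_equal(unname(f$lnc[1, 1:3]), unname(t$comp$ld_new[1, ]))
  expect_equal(unname(f$lnc[1, 4:5]), unname(unclass(t$lfj)[1, ]))
  expect_equal(unname(f$dis[2, 1:2]), unname(t$comp$ld_new[, 2]))
  expect_equal(unname(f$dis[2, 3:5]), unname(unclass(t$dsj)[, 2]))
  # dimension guards
  expect_error(build_raw_features(t$comp, t$dsj, t$dsj), "lfj must be")
})

test_that("all-zero network propagates to all-zero features", {
  ld <- adj(rep(0, 6), 2, 3)
  comp <- complement_merge(ld, matrix(0, 2, 3))
  z2 <- similarity_matrix(matrix(0, 2, 2, dimnames = list(c("L1", "L2"),
                                                          c("L1", "L2"))),
                          "jaccard")
  z3 <- similarity_matrix(matrix(0, 3, 3,
                                 dimnames = list(paste0("D", 1:3),
                                                 paste0("D", 1:3))),
                          "jaccard")
  f <- build_raw_features(comp, z2, z3)
  expect_true(all(f$lnc == 0) && all(f$dis == 0))
})

test_that("autoencoder training reduces MSE and is seed-reproducible", {
  set.seed(31)
  x <- matrix(stats::runif(60 * 18), 60, 18)
  enc1 <- train_autoencoder(x, latent_dim = 5, epochs = 60, seed = 42)
  enc2 <- train_autoencoder(x, latent_dim = 5, epochs = 60, seed = 42)
  lh <- enc1$loss_history
  expect_length(lh, 61)                       # recorded every epoch
  expect_lt(lh[length(lh)], lh[1])            # strict first-to-last decrease
  # non-increasing after smoothing over 5-epoch windows (SGD-noise tolerant)
  sm <- stats::filter(lh, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-4))
  # same seed -> encodings agree
  expect_equal(encode(enc1, x), encode(enc2, x), tolerance = 1e-6)
  # different seed -> different weights (sanity that the seed matters)
  enc3 <- train_autoencoder(x, latent_dim = 5, epochs = 60, seed = 43)
  expect_gt(max(abs(enc1$W1 - enc3$W1)), 0)
})

test_that("autoencoder learns low-rank structure beyond a constant predictor", {
  set.seed(77)
  u <- matrix(stats::runif(50 * 3), 50, 3)
  w <- matrix(stats::rexp(3 * 20), 3, 20)
  w <- sweep(w, 2, colSums(w), "/")       # convex mixing keeps X in [0, 1]
  x <- u %*% w
  enc <- train_autoencoder(x, latent_dim = 3, epochs = 400,
                           learning_rate = 5e-3, seed = 1)
  const_mse <- mean(apply(x, 2, function(col) mean((col - mean(col))^2)))
  expect_lt(enc$loss_history[length(enc$loss_history)], const_mse)
})

test_that("constant zero input drives reconstruction toward zero error", {
  x <- matrix(0, 20, 10)
  enc <- train_autoencoder(x, latent_dim = 2, epochs = 300,
                           learning_rate = 1e-2, seed = 3)
  expect_lt(enc$loss_history[length(enc$loss_history)],
            enc$loss_history[1] / 10)
})

test_that("encode is a deterministic row-wise map with width checks", {
  set.seed(13)
  x <- matrix(stats::runif(12 * 9), 12, 9,
              dimnames = list(paste0("L", 1:12), NULL))
  enc <- train_autoencoder(x, latent_dim = 4, epochs = 10, seed = 2)
  e1 <- encode(enc, x)
  expect_equal(dim(e1), c(12, 4))
  expect_identical(e1, encode(enc, x))
  perm <- sample(12)
  expect_equal(encode(enc, x[perm, ]), e1[perm, ])
  expect_error(encode(enc, x[, 1:5]), "width")
  # invalid training inputs
  expect_error(train_autoencoder(x, latent_dim = 9), "smaller")
  xb <- x; xb[1, 1] <- NA
  expect_error(train_autoencoder(xb, latent_dim = 3), "finite")
})
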