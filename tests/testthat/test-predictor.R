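encoded_stub <- function(names, p = 6, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(length(names) * p), length(names), p,
         dimnames = list(names, NULL))
}

test_that("balanced sampling draws valid, reproducible negatives", {
  set.seed(21)
  ld <- adj(c(1, 1, 0, 0,
              0, 1, 0, 0,
              0, 0, 0, 0,
              0, 0, 0, 0), 4, 4)
  lnc <- encoded_stub(rownames(ld)); dis <- encoded_stub(colnames(ld), seed = 2)
  s <- build_samples(ld, lnc, dis, seed = 5)
  expect_equal(length(s$labels), 6)
  expect_equal(sum(s$labels == 1), 3)
  expect_equal(sum(s$labels == 0), 3)
  # positives are exactly the LD == 1 cells; negatives among the 13 zeros
  m <- unclass_matrix_for_test <- unclass(ld)
  for (i in seq_len(nrow(s$pairs))) {
    cell <- m[s$pairs$lncRNA[i], s$pairs$disease[i]]
    expect_equal(cell, if (s$labels[i] == 1) 1L else 0L)
  }
  expect_false(anyDuplicated(s$pairs[, c("lncRNA", "disease")]) > 0)
  # feature row = lncRNA block then disease block
  expect_equal(unname(s$features[1, ]),
               unname(c(lnc[s$pairs$lncRNA[1], ], dis[s$pairs$disease[1], ])))
  # same seed -> identical draw; different seed is allowed to differ
  s2 <- build_samples(ld, lnc, dis, seed = 5)
  expect_identical(s$pairs, s2$pairs)
  # more positives than zeros -> reject
  ones <- adj(c(1, 1, 1, 0), 2, 2)
  expect_error(build_samples(ones, encoded_stub(c("L1", "L2")),
                             encoded_stub(c("D1", "D2"))), "unlabeled")
})

test_that("forest separates clustered classes and scores stay in [0, 1]", {
  set.seed(8)
  n <- 60; p <- 10
  x <- rbind(matrix(stats::rnorm(n / 2 * p, 1), n / 2, p),
             matrix(stats::rnorm(n / 2 * p, -1), n / 2, p))
  y <- rep(c(1L, 0L), each = n / 2)
  fit <- train_forest(list(features = x, labels = y), ntree = 100, seed = 1)
  s <- forest_score(fit, x)
  expect_true(all(s >= 0 & s <= 1))
  expect_gte(mean((s >= 0.5) == (y == 1)), 0.99)
  # reproducible under seed
  fit2 <- train_forest(list(features = x, labels = y), ntree = 100, seed = 1)
  expect_equal(forest_score(fit2, x), s)
  expect_error(train_forest(list(features = x, labels = rep(1L, n))),
               "single class")
  expect_error(train_forest(list(features = x, labels = y), mtry = 99),
               "mtry")
})

test_that("cross-validation partitions samples and hits the analytic limits", {
  set.seed(9)
  n <- 60; p <- 8
  x <- rbind(matrix(stats::rnorm(n / 2 * p, 1.5), n / 2, p),
             matrix(stats::rnorm(n / 2 * p, -1.5), n / 2, p))
  y <- rep(c(1L, 0L), each = n / 2)
  cv <- cross_validate(list(features = x, labels = y), k = 5, seed = 3,
                       classifier = forest_classifier(ntree = 100))
  expect_setequal(unique(cv$folds), 1:5)
  expect_equal(as.vector(table(cv$folds)), rep(12, 5))  # stratified partition
  expect_equal(cv$mean_metrics[["auc"]], 1)             # separable limit
  expect_true(all(unlist(cv$fold_metrics) >= 0 & unlist(cv$fold_metrics) <= 1))
  expect_equal(unname(cv$mean_metrics["auc"]),
               mean(cv$fold_metrics$auc))               # mean of folds
  # per-fold AUC equals the exhaustive pair-counting oracle on held-out scores
  for (f in 1:5) {
    te <- cv$folds == f
    expect_equal(cv$fold_metrics$auc[f],
                 oracle_auc(cv$scores[te], y[te]), tolerance = 1e-14)
  }
  # degenerate ranking: identical scores -> AUC 0.5
  flat <- list(label = "flat",
               fit = function(samples, seed) NULL,
               score = function(model, x) rep(0.5, nrow(x)))
  cvf <- cross_validate(list(features = x, labels = y), k = 5, seed = 3,
                        classifier = flat)
  expect_equal(cvf$mean_metrics[["auc"]], 0.5)
  expect_error(cross_validate(list(features = x, labels = y), k = 40),
               "exceeds")
})

test_that("label permutation drives CV AUC to the null level", {
  set.seed(10)
  n <- 80; p <- 8
  x <- rbind(matrix(stats::rnorm(n / 2 * p, 1.5), n / 2, p),
             matrix(stats::rnorm(n / 2 * p, -1.5), n / 2, p))
  y <- sample(rep(c(1L, 0L), each = n / 2))   # permuted labels
  cv <- cross_validate(list(features = x, labels = y), k = 5, seed = 4,
                       classifier = forest_classifier(ntree = 100))
  expect_gt(cv$mean_metrics[["auc"]], 0.3)
  expect_lt(cv$mean_metrics[["auc"]], 0.7)
})

test_that("candidate ranking excludes known pairs, truncates and breaks ties", {
  set.seed(12)
  ld <- adj(c(1, 0, 0,
              0, 0, 0,
              1, 0, 0,
              0, 0, 0), 4, 3)
  lnc <- encoded_stub(rownames(ld), seed = 3)
  dis <- encoded_stub(colnames(ld), seed = 4)
  s <- build_samples(ld, lnc, dis, seed = 1)
  fit <- train_forest(s, ntree = 50, seed = 1)
  r <- rank_candidates(fit, ld, lnc, dis, "D1", top_n = 10)
  expect_equal(sort(r$lncRNA), c("L2", "L4"))        # known pairs excluded
  expect_true(all(diff(r$score) <= 0))
  expect_error(rank_candidates(fit, ld, lnc, dis, "nope"), "unknown disease")
  # all-equal scores -> deterministic name order
  const <- list(p = ncol(s$features))
  class(const) <- "gclda_forest"
  r2 <- rank_candidates(const, ld, lnc, dis, "D2", top_n = 2,
                        score_fun = function(cl, x) rep(0.7, nrow(x)))
  expect_equal(r2$lncRNA, c("L1", "L2"))
})

test_that("held-out planted partners rank above a random baseline", {
  net <- small_planted_network(seed = 3, holdout = 0.2)
  fit <- small_fit(net, seed = 3)
  truth <- net$truth
  expect_gt(nrow(truth), 5)
  # mean normalized rank of held-out partners across their diseases
  norm_ranks <- numeric(0)
  for (dz in unique(truth$disease)) {
    r <- rank_candidates(fit$forest, fit$LD, fit$lnc_enc, fit$dis_enc, dz,
                         top_n = nrow(fit$LD))
    want <- truth$lncRNA[truth$disease == dz]
    norm_ranks <- c(norm_ranks, match(want, r$lncRNA) / nrow(r))
  }
  obs <- mean(norm_ranks)
  # null: 100 random rank assignments of the same size
  set.seed(99)
  null <- replicate(100, mean(stats::runif(length(norm_ranks))))
  expect_lt(obs, stats::quantile(null, 0.05))
})
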