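test_that("generated layers are binary, shape-coherent and seeded", {
  cfg <- synthetic_config(l = 25, m = 30, d = 20, rank = 4,
                          ld_density = 0.1, lm_density = 0.15,
                          md_density = 0.15, seed = 11)
  net <- generate_network(cfg)
  expect_equal(dim(net$LD), c(25, 20))
  expect_equal(dim(net$LM), c(25, 30))
  expect_equal(dim(net$MD), c(30, 20))
  expect_true(all(unclass(net$LD) %in% 0:1))
  # alignment-compatible: the product is defined and LD-shaped
  out <- align_layers(net$LD, net$MD, net$LM)
  expect_equal(dim(unclass(out$LM) %*% unclass(out$MD)), dim(out$LD))
  # quantile thresholding hits the target density within 1%
  expect_equal(sum(net$LD), round(0.1 * 25 * 20),
               tolerance = 0.01 * 25 * 20)
  # seeded determinism
  net2 <- generate_network(cfg)
  expect_identical(unclass(net$LD), unclass(net2$LD))
  expect_identical(unclass(net$LM), unclass(net2$LM))
  expect_identical(unclass(net$MD), unclass(net2$MD))
  # invalid configs rejected
  expect_error(synthetic_config(l = 5, m = 5, d = 5, rank = 9))
  expect_error(synthetic_config(ld_density = 0))
})

test_that("noise flipping and holdout behave as configured", {
  cfg0 <- synthetic_config(l = 30, m = 20, d = 25, rank = 3, ld_density = 0.1,
                           lm_density = 0.2, md_density = 0.2, seed = 2)
  base <- generate_network(cfg0)
  cfgn <- cfg0; cfgn$noise_flip_rate <- 0.05
  noisy <- generate_network(cfgn)
  expect_equal(sum(unclass(noisy$LD) != unclass(base$LD)),
               round(0.05 * 30 * 25))
  cfgh <- cfg0; cfgh$holdout_fraction <- 0.2
  held <- generate_network(cfgh)
  expect_equal(nrow(held$truth), round(0.2 * sum(base$LD)))
  # held-out pairs were ones in the base network, zeros now
  for (i in seq_len(nrow(held$truth)))
    expect_equal(unclass(held$LD)[held$truth$lncRNA[i],
                                  held$truth$disease[i]], 0L)
  expect_equal(sum(held$LD), sum(base$LD) - nrow(held$truth))
})

test_that("shared latent factors make the complement track held-out truth", {
  for (seed in 1:3) {
    net <- generate_network(synthetic_config(
      l = 40, m = 50, d = 30, rank = 3, ld_density = 0.08,
      lm_density = 0.12, md_density = 0.12, holdout_fraction = 0.15,
      seed = seed))
    lmd <- suppressWarnings(geometric_complement(net$LM, net$MD))
    held <- unclass(net$LD) * 0
    held[cbind(match(net$truth$lncRNA, rownames(held)),
               match(net$truth$disease, colnames(held)))] <- 1
    cand <- unclass(net$LD) == 0          # truth lives among the zeros
    rho <- stats::cor(lmd[cand], held[cand], method = "spearman")
    expect_gt(rho, 0)
  }
})

test_that("fixture suite is regenerated byte-identically with oracle values", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture_suite(d1)
  make_fixture_suite(d2)
  files <- list.files(d1)
  expect_true(all(c("jaccard_rows.csv", "lmd_2x2_lm.csv",
                    "planted_ld.csv") %in% files))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # expected files hold the hand-computed values
  expect_equal(as.numeric(readLines(file.path(d1, "jaccard_rows.expected.txt"))),
               1 / 3, tolerance = 1e-15)
  lmd <- as.matrix(utils::read.csv(file.path(d1, "lmd_2x2.expected.csv"),
                                   header = FALSE))
  expect_equal(unname(lmd), matrix(c(0.5, 1 / 3, 1 / 3, 0.5), 2, 2),
               tolerance = 1e-15)
  # fixture inputs reproduce their expected outputs through the package
  a <- read_adjacency(file.path(d1, "jaccard_rows.csv"), "dense",
                      "lncRNA", "disease")
  expect_equal(jaccard_similarity(a, "rows")["L1", "L2"], 1 / 3,
               tolerance = 1e-12)
  # the fixtures shipped with the package are the regenerated ones
  shipped <- system.file("extdata", package = "gclda")
  for (f in files)
    expect_identical(readLines(file.path(shipped, f)),
                     readLines(file.path(d1, f)))
})
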