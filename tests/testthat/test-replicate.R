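test_that("absolute correlation matrices have the contract shape", {
  set.seed(71)
  m <- matrix(rnorm(4 * 300), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:300)))
  m[2, ] <- -m[1, ]                      # perfect anticorrelation
  cc <- abs_corr_matrix(m, paste0("g", 1:4))
  expect_equal(cc["g1", "g2"], 1)
  expect_true(isSymmetric(unname(cc)))
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_true(all(cc >= 0 & cc <= 1))
  # a gene against an independent permutation of itself decorrelates
  big <- matrix(0, nrow = 2, ncol = 1000,
                dimnames = list(c("a", "b"), NULL))
  big[1, ] <- rnorm(1000)
  big[2, ] <- sample(big[1, ])
  expect_lt(abs_corr_matrix(big, c("a", "b"))["a", "b"], 0.1)
  # absent genes are dropped with a count; too few genes error
  expect_equal(attr(abs_corr_matrix(m, c("g1", "g2", "zz")), "n_dropped"),
               1)
  expect_error(abs_corr_matrix(m, c("g1", "zz")), "fewer than 2")
})

test_that("background sampling is seeded and sized correctly", {
  set.seed(72)
  m <- matrix(rnorm(30 * 100), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  v1 <- background_corr_sample(m, set_size = 2, n_draws = 5, seed = 3)
  expect_length(v1, 5)                   # one off-diagonal pair per draw
  expect_identical(v1, background_corr_sample(m, 2, 5, seed = 3))
  expect_error(background_corr_sample(m, set_size = 50, seed = 1),
               "smaller than set size")
})

test_that("background |r| follows the null correlation distribution", {
  set.seed(73)
  n <- 60
  m <- matrix(rnorm(80 * n), nrow = 80,
              dimnames = list(sprintf("g%02d", 1:80), NULL))
  v <- background_corr_sample(m, set_size = 10, n_draws = 30, seed = 9)
  # under independence r^2 ~ Beta(1/2, (n-2)/2); one-sample KS against
  # that closed-form null (duplicate gene pairs across draws repeat
  # values, hence the suppressed ties warning)
  p <- suppressWarnings(
    ks.test(v, function(q) pbeta(q^2, 0.5, (n - 2) / 2))$p.value)
  expect_gt(p, 0.01)
})

test_that("Kruskal-Wallis comparison matches the hand rank formula", {
  res <- compare_distributions(c(1, 2, 3), c(4, 5, 6))
  # R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-10)
  expect_equal(res$pvalue, pchisq(27 / 7, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  same <- compare_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$pvalue, 1)
  expect_error(compare_distributions(numeric(0), 1), "nonempty")
})

test_that("discovery leaf order groups planted clusters and transfers", {
  # block-diagonal discovery matrix with two planted clusters
  genes <- sprintf("g%02d", 1:6)
  d <- matrix(0.05, 6, 6, dimnames = list(genes, genes))
  d[1:3, 1:3] <- 0.9
  d[4:6, 4:6] <- 0.9
  diag(d) <- 1
  shuffled <- genes[c(1, 4, 2, 5, 3, 6)]
  d <- d[shuffled, shuffled]
  ord <- transfer_cluster_order(d, d)
  expect_setequal(ord$leaf_order, genes)
  pos <- match(genes, ord$leaf_order)
  expect_equal(abs(diff(range(pos[1:3]))), 2)   # cluster 1 contiguous
  expect_equal(abs(diff(range(pos[4:6]))), 2)   # cluster 2 contiguous
  expect_identical(ord$discovery, ord$replication)
  expect_error(transfer_cluster_order(d[1, , drop = FALSE], d),
               "fewer than 2")
})

test_that("replication detects preserved networks end to end", {
  cfg <- sim_config(n_samples = 300, n_genes_per_tissue = 200,
                    n_tissues = 1, n_trans_genes = 0, n_regulators = 1,
                    targets_per_regulator = 20, edge_effect_size = 0.8,
                    replication_attenuation = 1, seed = 74)
  co <- simulate_cohort(cfg)
  repl <- simulate_replication(co$truth, cfg)
  tg <- co$truth$true_edges$target
  rr <- replicate_network(tg, co$expression[[1]], repl[[1]],
                          regulator = "R", dataset = "D", seed = 5)
  expect_lt(rr$pvalue, 1e-6)
  expect_equal(rr$n_targets, 20)
  expect_setequal(rr$leaf_order, tg)
  expect_gt(mean(rr$target_corr), mean(rr$background_corr))
})
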