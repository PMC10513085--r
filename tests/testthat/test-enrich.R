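test_that("Fisher p-values equal full hypergeometric enumeration", {
  # the table at its expectation has p = 1 and odds ratio 1
  bg <- sprintf("g%03d", 1:100)
  fe <- fisher_enrichment(bg[1:10], c(bg[1], bg[11:19]), bg)
  expect_identical(unname(as.vector(fe$table)), c(1L, 9L, 9L, 81L))
  expect_equal(fe$pvalue, 1)
  expect_equal(fe$odds_ratio, 1, tolerance = 1e-6)
  # network targets equal to the TF set: smallest p for those margins
  fe2 <- fisher_enrichment(bg[1:10], bg[1:10], bg)
  expect_equal(fe2$pvalue, enum_fisher_p(10, 0, 0, 90), tolerance = 1e-12)
  # disjoint TF set leaves a zero column: p = 1 by convention
  fe3 <- fisher_enrichment(bg[1:10], "not_in_background", bg)
  expect_equal(fe3$pvalue, 1)
  expect_error(fisher_enrichment(bg[1:2], bg[1:2], character(0)),
               "empty background")
  # random tables against the enumeration oracle
  set.seed(61)
  for (i in 1:25) {
    a <- sample(0:30, 1); b <- sample(0:40, 1)
    c_ <- sample(0:40, 1); d <- sample(0:80, 1)
    if (a + b == 0 || a + c_ == 0) next
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(p, enum_fisher_p(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("the exact test is symmetric under transposition", {
  set.seed(62)
  for (i in 1:10) {
    m <- matrix(sample(0:30, 4, replace = TRUE), 2)
    expect_equal(fisher.test(m)$p.value, fisher.test(t(m))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("enrichment scan covers TF sets x regulators x FDR levels", {
  mk_net <- function(fdr, targets) {
    structure(list(edges = data.frame(regulator = "r1", target = targets,
                                      tissue = "SF",
                                      posterior = 1),
                   regulators = "r1", tissue = "SF", fdr_threshold = fdr,
                   achieved_fdr = 0, dropped_regulators = character(0)),
              class = "cortnet_network")
  }
  bg <- sprintf("g%03d", 1:200)
  set.seed(63)
  tf <- list(TFA = bg[1:20])
  nets <- list("0.1" = mk_net(0.1, bg[1:30]), "0.15" = mk_net(0.15, bg[1:50]))
  res <- enrichment_scan(nets, tf, bg)
  expect_equal(nrow(res), 2)
  expect_setequal(res$fdr_level, c("0.1", "0.15"))
  expect_true(all(res$a + res$b + res$c + res$d == 200))
  # targets drawn 50% from a TF set covering 10% of background: enriched
  tf_set <- bg[1:20]
  targets <- c(sample(tf_set, 15), sample(setdiff(bg, tf_set), 15))
  hit <- enrichment_scan(list("0.1" = mk_net(0.1, targets)),
                         list(TFA = tf_set), bg)
  expect_lt(hit$pvalue, 0.01)
  expect_gt(hit$odds_ratio, 1)
})
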