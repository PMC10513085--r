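scored_edges <- function(co, tissue = names(co$expression)[1]) {
  gi <- co$gene_info
  regs <- gi$gene[gi$role == "regulator"]
  do.call(rbind, lapply(regs, function(r) {
    score_all_pairs(r, co$truth$instrument_map[[r]], co$genotypes,
                    co$expression[[tissue]], tissue)
  }))
}

test_that("edge scoring covers every other gene exactly once", {
  co <- small_cohort(seed = 51, n = 200, genes = 120, tissues = 1,
                     regulators = 1, targets = 6)
  reg <- co$gene_info$gene[co$gene_info$role == "regulator"]
  ed <- score_all_pairs(reg, co$truth$instrument_map[[reg]],
                        co$genotypes, co$expression[[1]], "LIV")
  expect_equal(nrow(ed), 119)                      # G - 1, no self-edge
  expect_false(reg %in% ed$target)
  expect_true(all(ed$posterior >= 0 & ed$posterior <= 1))
  # planted targets outscore white-noise genes
  tg <- co$truth$true_edges$target
  null_genes <- co$gene_info$gene[co$gene_info$role == "null"]
  expect_gt(min(ed$posterior[ed$target %in% tg]),
            quantile(ed$posterior[ed$target %in% null_genes], 0.95))
  expect_lt(mean(ed$posterior[ed$target %in% null_genes]), 0.5)
  # monomorphic instrument is refused
  geno <- co$genotypes
  geno[, co$truth$instrument_map[[reg]]] <- 1L
  expect_error(score_all_pairs(reg, co$truth$instrument_map[[reg]],
                               geno, co$expression[[1]], "LIV"),
               "monomorphic")
})

test_that("network building prunes small regulators and keeps FDR honest", {
  co <- small_cohort(seed = 52, n = 250, genes = 150, tissues = 1,
                     regulators = 3, targets = c(8, 8, 2))
  ed <- scored_edges(co)
  nw <- build_network(ed, 0.10, min_targets = 4)
  regs <- co$gene_info$gene[co$gene_info$role == "regulator"]
  expect_setequal(nw$regulators, regs[1:2])      # 2-target decoy removed
  expect_true(regs[3] %in% nw$dropped_regulators)
  expect_lte(1 - mean(nw$edges$posterior), nw$fdr_threshold)
  expect_equal(nw$achieved_fdr, 1 - mean(nw$edges$posterior))
  # a regulator with three surviving edges is removed entirely
  toy <- data.frame(regulator = c(rep("r1", 5), rep("r2", 3)),
                    target = paste0("t", 1:8), tissue = "LIV",
                    posterior = c(rep(1, 5), rep(0.97, 3)))
  nw2 <- build_network(toy, 0.10, min_targets = 4)
  expect_identical(nw2$regulators, "r1")
  expect_equal(nrow(nw2$edges), 5)
  # all-posterior-one edges are all retained with achieved FDR 0
  toy1 <- data.frame(regulator = "r", target = paste0("t", 1:10),
                     tissue = "LIV", posterior = 1)
  nw3 <- build_network(toy1, 0.10)
  expect_equal(nrow(nw3$edges), 10)
  expect_equal(nw3$achieved_fdr, 0)
  expect_error(build_network(data.frame(regulator = "r", target = "r",
                                        tissue = "L", posterior = 1),
                             0.1), "self-edges")
})

test_that("achieved FDR stays within threshold after pruning re-check", {
  # pruning removes a high-posterior pair, forcing the re-selection loop
  toy <- data.frame(
    regulator = c(rep("big", 6), "tiny", "tiny"),
    target = paste0("t", 1:8), tissue = "LIV",
    posterior = c(0.95, 0.92, 0.90, 0.88, 0.86, 0.85, 1, 1))
  nw <- build_network(toy, 0.10, min_targets = 4)
  expect_lte(nw$achieved_fdr, 0.10 + 1e-12)
  expect_false("tiny" %in% nw$regulators)
})

test_that("networks are deterministic and export to GraphML", {
  co <- small_cohort(seed = 53, n = 200, genes = 120, tissues = 1,
                     regulators = 2, targets = 6)
  ed <- scored_edges(co)
  nw1 <- build_network(ed, 0.10)
  nw2 <- build_network(ed[sample(nrow(ed)), ], 0.10)
  expect_identical(nw1$edges, nw2$edges)
  st <- network_stats(nw1)
  expect_equal(sum(st$regulator_targets), st$total_targets[1])
  expect_equal(nrow(st), length(nw1$regulators))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(nw1, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(nw1$edges))
  # empty network
  empty <- build_network(ed[0, ], 0.10)
  expect_equal(nrow(network_stats(empty)), 0)
})
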