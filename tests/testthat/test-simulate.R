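test_that("configuration invariants are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(sim_config(replication_attenuation = 1.5), "attenuation")
  expect_error(sim_config(noise_sd = 0))
  expect_error(sim_config(n_genes_per_tissue = 10, n_regulators = 3,
                          targets_per_regulator = 10), "universe too small")
})

test_that("truth ledger counts are forced by the configuration", {
  co <- simulate_cohort(sim_config(n_samples = 60, n_genes_per_tissue = 60,
                                   n_tissues = 1, n_regulators = 3,
                                   targets_per_regulator = 10, seed = 2))
  expect_equal(nrow(co$truth$true_edges), 30)
  expect_equal(length(co$truth$instrument_map), 3)
  expect_true(all(co$truth$true_edges$regulator %in%
                    names(co$truth$instrument_map)))
  # trans pairs and edges are disjoint relations by construction
  expect_length(intersect(
    paste(co$truth$true_trans_pairs$snp, co$truth$true_trans_pairs$gene),
    paste(co$truth$true_edges$regulator, co$truth$true_edges$target)), 0)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- sim_config(n_samples = 80, n_genes_per_tissue = 50, seed = 9)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  co <- simulate_cohort(cfg)
  expect_identical(simulate_replication(co$truth, cfg),
                   simulate_replication(co$truth, cfg))
})

test_that("planted trans effects are recovered by least squares", {
  cfg <- sim_config(n_samples = 300, n_genes_per_tissue = 80,
                    n_trans_genes = 5, trans_effect_size = 0.8, seed = 14)
  co <- simulate_cohort(cfg)
  tp <- co$truth$true_trans_pairs
  tp <- tp[tp$tissue == names(co$expression)[1], ][1, ]
  fit <- summary(lm(co$expression[[1]][tp$gene, ] ~
                      co$genotypes[, tp$snp]))
  expect_lt(abs(fit$coefficients[2, 1] - 0.8),
            3 * fit$coefficients[2, 2])
})

test_that("within-block SNPs are in linkage disequilibrium", {
  co <- simulate_cohort(sim_config(n_samples = 400, n_snps_per_block = 4,
                                   n_blocks = 2, n_genes_per_tissue = 30,
                                   n_trans_genes = 0, n_regulators = 0,
                                   seed = 3))
  g <- co$genotypes[, co$snp_info$snp[which(co$snp_info$block == 1)]]
  cors <- cor(g)[upper.tri(diag(4))]
  expect_gt(min(cors), 0.3)
})

test_that("replication attenuation scales target co-expression", {
  base <- list(n_samples = 400, n_genes_per_tissue = 120, n_tissues = 1,
               n_trans_genes = 0, n_regulators = 1,
               targets_per_regulator = 20, edge_effect_size = 0.8,
               seed = 5)
  for (att in c(0, 1)) {
    cfg <- do.call(sim_config, c(base, replication_attenuation = att))
    co <- simulate_cohort(cfg)
    repl <- simulate_replication(co$truth, cfg)[[1]]
    tg <- unique(co$truth$true_edges$target)
    bg <- co$gene_info$gene[co$gene_info$role == "null"][1:20]
    mt <- mean(abs(cor(t(repl[tg, ])))[upper.tri(diag(20))])
    mb <- mean(abs(cor(t(repl[bg, ])))[upper.tri(diag(20))])
    if (att == 0) expect_lt(abs(mt - mb), 0.05) else expect_gt(mt, mb + 0.2)
  }
})

test_that("true trans-pair LLRs stochastically dominate null-pair LLRs", {
  co <- simulate_cohort(sim_config(
    n_samples = 300, n_snps_per_block = 2, n_blocks = 2,
    n_genes_per_tissue = 250, n_trans_genes = 100,
    trans_effect_size = 0.5, n_regulators = 0, seed = 15))
  tp <- co$truth$true_trans_pairs
  tp <- tp[tp$tissue == names(co$expression)[1], ]
  expr <- supernormalize_matrix(co$expression[[1]])
  llr_true <- vapply(seq_len(nrow(tp)), function(i) {
    linkage_llr(co$genotypes[, tp$snp[i]], expr[tp$gene[i], ])
  }, numeric(1))
  nulls <- co$gene_info$gene[co$gene_info$role == "null"][1:100]
  llr_null <- vapply(seq_along(nulls), function(i) {
    linkage_llr(co$genotypes[, co$snp_info$snp[1]], expr[nulls[i], ])
  }, numeric(1))
  expect_lt(wilcox.test(llr_true, llr_null,
                        alternative = "greater")$p.value, 0.01)
})

test_that("GWAS p-values separate locus SNPs from the rest", {
  co <- simulate_cohort(sim_config(n_samples = 60, n_genes_per_tissue = 60,
                                   n_null_snps = 5, seed = 6))
  locus <- co$snp_info$snp[!is.na(co$snp_info$block)]
  others <- setdiff(co$snp_info$snp, locus)
  expect_true(all(co$truth$gwama_pvalues[locus] < 5e-8))
  expect_true(all(co$truth$gwama_pvalues[others] > 1e-6))
})

test_that("synthetic catalogs mark exactly the planted regulators", {
  co <- small_cohort(seed = 7)
  cat_ <- synthetic_gr_catalog(co)
  regs <- co$gene_info$gene[co$gene_info$role == "regulator"]
  sc <- score_gr_evidence(co$gene_info$gene, "LIV", cat_)
  expect_true(all(sc$score[sc$gene %in% regs] >= 1))
  tf <- synthetic_tf_sets(co)
  expect_length(tf, length(regs))
  for (r in regs) {
    tg <- co$gene_info$gene[!is.na(co$gene_info$regulator) &
                              co$gene_info$regulator == r]
    expect_true(all(tg %in% tf[[sprintf("TF_%s_syn", r)]]))
  }
})
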