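test_that("GWAS filtering uses a strict threshold and preserves order", {
  tab <- data.frame(snp = c("a", "b", "c"),
                    pval = c(4e-8, 5e-8, 6e-9))
  expect_identical(filter_gwas_snps(tab, 5e-8), c("a", "c"))
  expect_identical(filter_gwas_snps(tab[0, ], 5e-8), character(0))
  expect_error(filter_gwas_snps(data.frame(x = 1), 5e-8), "missing column")
  # planted locus SNPs all pass; at 5e-8 essentially no null SNP does
  co <- small_cohort(seed = 30)
  kept <- filter_gwas_snps(co$gwama, 5e-8)
  expect_setequal(kept, co$snp_info$snp[!is.na(co$snp_info$block)])
})

test_that("the scan is a flagged cartesian product with cis annotation", {
  co <- small_cohort(seed = 31, n = 120, genes = 110, tissues = 1,
                     regulators = 1, targets = 4)
  snps <- filter_gwas_snps(co$gwama, 5e-8)[1:3]
  # force a monomorphic SNP in a copy of the genotypes
  geno <- co$genotypes
  geno[, snps[2]] <- 1L
  rec <- scan_tissue(snps, geno, co$expression[[1]], "LIV",
                     snp_info = co$snp_info, gene_info = co$gene_info)
  expect_equal(nrow(rec), 3 * 110)
  expect_true(all(rec$status[rec$snp == snps[2]] == "monomorphic"))
  expect_true(all(is.na(rec$posterior[rec$snp == snps[2]])))
  expect_true(all(!is.na(rec$posterior[rec$snp != snps[2]])))
  # locus SNPs on chr 14 vs genes elsewhere: everything is trans
  expect_true(all(!rec$cis))
  expect_error(scan_tissue(snps, co$genotypes[1:10, ],
                           co$expression[[1]][, 1:10], "LIV"),
               "shared samples")
})

test_that("planted trans pairs outrank null pairs in the scan", {
  co <- small_cohort(seed = 32, n = 300, genes = 150, tissues = 1,
                     regulators = 1, targets = 4)
  snps <- filter_gwas_snps(co$gwama, 5e-8)
  rec <- scan_tissue(snps, co$genotypes, co$expression[[1]], "LIV",
                     snp_info = co$snp_info, gene_info = co$gene_info)
  tp <- co$truth$true_trans_pairs
  truth_key <- paste(tp$snp, tp$gene)
  lab <- paste(rec$snp, rec$gene) %in% truth_key
  expect_gt(min(rec$posterior[lab]), median(rec$posterior[!lab]))
})

test_that("global-FDR selection takes the documented posterior prefix", {
  recs <- data.frame(snp = c("s1", "s2", "s3"), gene = c("g1", "g2", "g3"),
                     posterior = c(0.99, 0.98, 0.50), selected = FALSE)
  sel <- select_by_global_fdr(recs, 0.10)
  expect_equal(sel$n_selected, 2)          # 1 - mean(.99,.98) = 0.015
  expect_equal(sel$achieved_fdr, 0.015)    # adding 0.50 gives 0.1767
  expect_lte(sel$achieved_fdr, sel$threshold)

  one <- select_by_global_fdr(data.frame(snp = "s", gene = "g",
                                         posterior = 0.5,
                                         selected = FALSE), 0.10)
  expect_equal(one$n_selected, 0)

  all1 <- select_by_global_fdr(data.frame(snp = letters[1:4],
                                          gene = letters[5:8],
                                          posterior = rep(1, 4),
                                          selected = FALSE), 0.10)
  expect_equal(all1$n_selected, 4)
  expect_equal(all1$achieved_fdr, 0)

  empty <- select_by_global_fdr(recs[0, ], 0.10)
  expect_equal(empty$n_selected, 0)
})

test_that("lowering the FDR threshold never enlarges the selection", {
  set.seed(33)
  recs <- data.frame(snp = sprintf("s%03d", 1:200),
                     gene = sprintf("g%03d", 1:200),
                     posterior = runif(200), selected = FALSE)
  sizes <- vapply(c(0.30, 0.20, 0.10, 0.05),
                  function(th) select_by_global_fdr(recs, th)$n_selected,
                  integer(1))
  expect_false(is.unsorted(rev(sizes)))
})

test_that("tissue sharing tabulations partition the selections", {
  mk <- function(genes, tissue, blocks) {
    data.frame(snp = paste0("s", seq_along(genes)), gene = genes,
               tissue = tissue, block = blocks, posterior = 1,
               selected = TRUE)
  }
  sels <- list(LIV = mk(c("g1", "g2"), "LIV", c(1, 2)),
               VAF = mk(c("g2", "g3"), "VAF", c(1, 1)))
  tab <- tabulate_sharing(sels)
  expect_equal(unname(tab$genes_per_tissue), c(2L, 2L))
  combos <- setNames(tab$tissue_combinations$n_genes,
                     tab$tissue_combinations$combination)
  expect_equal(combos[["LIV+VAF"]], 1L)   # g2 counted once, shared
  expect_equal(combos[["LIV"]], 1L)
  expect_equal(combos[["VAF"]], 1L)
  expect_equal(sum(tab$block_counts$n_associations), 4L)

  disjoint <- tabulate_sharing(list(A = mk("g1", "A", 1),
                                    B = mk("g2", "B", 1)))
  expect_false(any(grepl("\\+", disjoint$tissue_combinations$combination)))

  empty <- tabulate_sharing(list(LIV = sels$LIV[0, ]))
  expect_equal(unname(empty$genes_per_tissue), 0L)
})
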