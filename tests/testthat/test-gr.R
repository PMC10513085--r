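make_catalog <- function() {
  evidence_catalog(
    tf_db_sets = list(ENCODE = c("g1", "g3"), TRANSFAC = "g1",
                      CHEA = "g1"),
    chipseq_set = c("g2", "g3"),
    dex_de_set = "g3",
    murine_dex = data.frame(gene = c("g4", "g5", "g6"),
                            fc = c(2, 0.8, 3), pval = c(0.01, 0.01, 0.2)),
    applicability = gr_applicability(c("LIV", "SF", "VAF")))
}

test_that("the scoring rubric counts each criterion once, per tissue", {
  cat_ <- make_catalog()
  # three databases still score 1 (criterion 1 counts once)
  s <- score_gr_evidence("g1", "LIV", cat_)
  expect_equal(s$score, 1L)
  expect_equal(s$criteria, "1")
  # ChIP-seq evidence is inapplicable in liver
  expect_equal(score_gr_evidence("g2", "LIV", cat_)$score, 0L)
  expect_equal(score_gr_evidence("g2", "SF", cat_)$score, 1L)
  # database + ChIP-seq + dex in subcutaneous fat scores 3
  s3 <- score_gr_evidence("g3", "SF", cat_)
  expect_equal(s3$score, 3L)
  expect_equal(s3$criteria, "1,2,3")
  # murine criterion requires FC > 1 and p < 0.05, subcutaneous only
  expect_equal(score_gr_evidence("g4", "SF", cat_)$score, 1L)
  expect_equal(score_gr_evidence("g4", "VAF", cat_)$score, 0L)
  expect_equal(score_gr_evidence("g5", "SF", cat_)$score, 0L)  # FC <= 1
  expect_equal(score_gr_evidence("g6", "SF", cat_)$score, 0L)  # p >= 0.05
  expect_error(score_gr_evidence("g1", "BRAIN", cat_), "unknown tissue")
})

test_that("tissue masking never credits criteria 2-4 outside adipose", {
  cat_ <- make_catalog()
  sc_liv <- score_gr_evidence(paste0("g", 1:6), "LIV", cat_)
  expect_false(any(grepl("[234]", sc_liv$criteria)))
  sc_vaf <- score_gr_evidence(paste0("g", 1:6), "VAF", cat_)
  expect_false(any(grepl("4", sc_vaf$criteria)))
  # score always equals the number of criteria met
  for (sc in list(sc_liv, sc_vaf)) {
    n_crit <- ifelse(sc$criteria == "", 0L,
                     lengths(strsplit(sc$criteria, ",")))
    expect_equal(sc$score, n_crit)
  }
})

test_that("GR filtering keeps scored genes in rank order", {
  scores <- data.frame(gene = c("g1", "g2", "g3"), tissue = "SF",
                       score = c(2L, 0L, 1L), criteria = c("1,2", "", "1"))
  out <- filter_gr_trans_genes(data.frame(gene = c("g1", "g2", "g3"),
                                          tissue = "SF"), scores)
  expect_identical(out$gene, c("g1", "g3"))
  none <- filter_gr_trans_genes(data.frame(gene = "g2", tissue = "SF"),
                                scores)
  expect_equal(nrow(none), 0)
})

test_that("instrument selection is an argmax with threshold and reasons", {
  co <- small_cohort(seed = 41, n = 250, genes = 150, tissues = 1,
                     regulators = 2, targets = 5)
  gi <- co$gene_info
  regs <- gi$gene[gi$role == "regulator"]
  cand <- data.frame(gene = c(regs, gi$gene[gi$role == "null"][1]),
                     tissue = "LIV")
  out <- select_instrumented_regulators(
    cand, co$genotypes, co$expression, co$snp_info, gi,
    posterior_threshold = 0.75)
  # planted regulators keep their true instruments
  expect_setequal(out$gene, regs)
  expect_identical(out$instrument_snp[match(regs, out$gene)],
                   unname(co$truth$instrument_map[regs]))
  expect_true(all(out$instrument_posterior >= 0.75))
  # the null gene has no cis SNP and is dropped with a reason
  dropped <- attr(out, "dropped")
  expect_equal(dropped$reason, "no_cis_snp")
})
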