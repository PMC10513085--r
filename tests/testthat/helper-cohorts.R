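# Shared small fixtures, built in code.

# A compact cohort with planted trans genes, regulators and targets.
small_cohort <- function(seed = 1, n = 200, genes = 150, tissues = 2,
                         regulators = 2, targets = 8, effect = 0.8) {
  simulate_cohort(sim_config(
    n_samples = n, n_genes_per_tissue = genes, n_tissues = tissues,
    n_regulators = regulators, targets_per_regulator = targets,
    trans_effect_size = effect, edge_effect_size = effect, seed = seed))
}

# A pure-null single-SNP cohort for calibration checks.
null_cohort <- function(seed = 1, n = 200, genes = 1000) {
  simulate_cohort(sim_config(
    n_samples = n, n_snps_per_block = 1, n_blocks = 1,
    maf_range = c(0.3, 0.4), n_tissues = 1, n_genes_per_tissue = genes,
    n_trans_genes = 0, n_regulators = 0, seed = seed))
}

# Rank-based AUROC (Mann-Whitney form), used as the recovery oracle.
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Brute-force two-sided Fisher p: enumerate all tables with the observed
# margins and sum hypergeometric point probabilities not exceeding the
# observed one (relative tolerance absorbs floating-point ties of
# symmetric tables).
enum_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b
  r2 <- c_ + d
  k <- a + c_
  xs <- max(0, k - r2):min(r1, k)
  probs <- stats::dhyper(xs, r1, r2, k)
  p_obs <- stats::dhyper(a, r1, r2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
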