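---
title: "Methods: instrument-based trans-eQTL networks and their replication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrument-based trans-eQTL networks and their replication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A handful of SNPs at a single trait-associated locus — here, variants
linked to circulating cortisol — may alter gene expression far from the
locus, across several tissues, by changing the delivery of a hormone to
those tissues.  The analysis this package implements asks four questions
in sequence: which genes respond in trans to the trait-associated SNPs in
each tissue; which of those trans-genes carry prior evidence of
regulation by the glucocorticoid receptor (GR), the transcription factor
the hormone activates; which GR-linked trans-genes causally drive wider
transcriptional networks in their tissue; and whether the co-expression
signature of those networks is present in independent cohorts that have
expression data only.

# Model and tests

## Supernormalization

All expression vectors are transformed to `qnorm((rank - 0.5)/n)` with
midranks for ties, then centred and rescaled to unit sample variance.
The likelihood-ratio machinery below assumes Gaussian residuals; forcing
an exactly standard-normal marginal makes the tests distribution-free
with respect to the raw expression scale at the cost of discarding
information carried by the marginal shape.  The transform is idempotent
and invariant under monotone changes of scale, so it is safe to apply to
already-normalized data.

## The likelihood-ratio family

Every test compares two nested Gaussian models by maximum likelihood and
reports `LLR = (n/2)·ln(σ̂²_null / σ̂²_alt) ≥ 0`.  With a categorical
genotype `E` (`k` observed dosage categories), a regulator `A` and a
candidate target `B`:

* **primary / secondary linkage** — `y ~ 1` versus `y ~ E` (one mean per
  genotype group), applied to `A` and `B` respectively;
* **conditional independence** — `B ~ A` versus `B ~ E + A`; a small
  statistic supports `B ⊥ E | A`, i.e. full mediation of the instrument's
  effect by the regulator.  Its *null* is the hypothesis of interest, so
  the reported posterior is the local FDR itself;
* **relevance** — `B ~ 1` versus `B ~ E + A`;
* **controlled** — `B ~ E` versus `B ~ E + A`, which asks whether the
  regulator explains the target beyond any direct genotype effect.

Under each null, the variance-reduction fraction `1 - exp(-2·LLR/n)`
follows a Beta distribution whose shapes come from the parameter counts
of the nested pair (for linkage, `Beta((k-1)/2, (n-k)/2)`); p-values are
analytic, and the permutation test agrees with them to Monte-Carlo error
(a property the test suite checks).

Assumptions worth keeping in mind: additive genotype coding with one mean
per category (no dominance model is fitted, but none is imposed either),
linear regulator-to-target relations, and independent samples.  Missing
genotypes are expected to be handled upstream by listwise deletion per
SNP-gene pair; the functions refuse missing values rather than guessing.

## From statistics to posteriors

Statistics are priced within an *ensemble* sharing one null — by default
one instrument SNP against all genes of a tissue (at least 100
statistics; pool instruments with equal `(n, k)` when scans are smaller).
The posterior of the alternative is one minus the empirical local FDR,

    lfdr(L) = π₀ · f₀(L) / f(L),

estimated as follows:

1. **Binning on the null-CDF scale.**  Each statistic maps to its
   analytic p-value; bins are p-value deciles across the null bulk plus
   half-decade bins in the tail down to a tenth of `1/m`.  Every bin then
   has a known null mass, and the observed-to-expected mass ratio
   estimates `f/f₀` directly.  (Equal-width bins on the LLR axis were
   rejected: a single large statistic stretches the range and merges
   moderate signals into bins dominated by the genuine null tail.)
2. **Monotonization.**  The per-bin ratio is made nondecreasing in LLR by
   null-mass-weighted isotonic regression (pool-adjacent-violators) — a
   binned Grenander-type monotone density-ratio estimate.  Posteriors are
   therefore monotone in the statistic, and exact ties share a value.
3. **Null proportion by central matching.**  Under the "zero assumption"
   the mixture is treated as purely null throughout the null's central
   90% mass; the ratio level at that anchor calibrates `π₀`, pinning the
   local FDR to 1 across the null bulk so that only statistics beyond it
   can earn posterior above zero.  An independent Storey-type estimate
   (`π₀ = #{p > λ}/((1-λ)m)`, `λ = 0.5`) is available via
   `pi0_method = "storey"`; it is noisier at ensemble sizes near 10³, and
   whenever it undershoots, every bulk statistic inherits a spurious
   posterior floor of the relative error — the central anchor removes
   that failure mode at the cost of mild conservatism for weak signals
   inside the null bulk.

## The combined causal posterior

The default composite is `P(A→B) = (P₂·P₅ + P₄)/2`: confidence that the
target responds to the instrument and that the regulator adds explanatory
power beyond it, averaged with the relevance posterior so that hidden
confounders acting on both genes do not veto an edge.  The conservative
alternative `P₂·P₃` (secondary linkage times the conditional-independence
posterior) additionally demands full mediation and is exposed through
`combine = "conservative"`; it is stricter under pleiotropy but loses
power whenever a real edge coexists with a weak direct genotype effect.

## Selection under a global FDR

Records are ranked by posterior (ties broken lexicographically by ids for
determinism) and the largest prefix whose estimated global FDR
`1 - mean(posterior)` stays within the nominal level is selected.  This
Bayesian global FDR follows directly from the posterior semantics: the
expected fraction of false selections is the mean null probability of the
selected set.  Networks additionally prune regulators with fewer than
`min_targets = 4` surviving edges; because pruning can remove
above-average edges, the achieved FDR is recomputed and the selection
re-run on the remaining regulators' candidates until a fixed point — the
reported network always satisfies its threshold by construction.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `gwas_p_threshold` | 5e-8 | p-value | genome-wide significance for the SNP filter (strict `<`) |
| `trans_fdr` | 0.15 | global FDR | lenient trans discovery; trans effects are weak and a biological (evidence) filter follows |
| `network_fdr` | 0.10 | global FDR | stricter edge selection; no downstream biological filter |
| `min_targets` | 4 | count | a "network regulator" must drive a non-trivial target set |
| `instrument_posterior` | 0.75 | posterior | minimum primary-linkage posterior for a valid cis instrument; weak instruments break the causal tests |
| `cis_window` | 1e6 | bp | cis/trans boundary and instrument search window |
| `min_stats` | 100 | count | smallest ensemble for local-FDR estimation |
| `lambda` | 0.5 | p-value | Storey tuning when `pi0_method = "storey"` |
| `n_bg_draws` | 1 | count | random background sets per replication comparison (one mirrors the original procedure; more stabilize the background at the cost of fidelity) |

# The synthetic cohorts

`simulate_cohort()` draws genotypes per SNP as sums of two haplotype
alleles; within an LD block every SNP copies a latent block haplotype
with per-allele flip probability `(1 - ld_r)/2` (default `ld_r = 0.8`),
giving strong but imperfect within-block correlation.  Expression is
standardized Gaussian noise (`noise_sd = 1`) plus planted effects: trans
genes receive `trans_effect_size × dosage` of an assigned locus SNP;
regulators are themselves trans-genes and additionally receive a cis
effect from a private instrument SNP placed within 100 kb of the gene;
targets receive `edge_effect_size × regulator expression` — a depth-1
linear structural-equation model.  Locus SNPs get GWAS p-values
`10^-U, U ~ Uniform(8, 30)` so they pass the significance filter; all
other SNPs get `Uniform(0, 1)`.  The replication cohort redraws samples
over the same gene universe with edge effects multiplied by
`replication_attenuation` and carries no genotypes, mirroring
expression-only public cohorts.  A truth ledger records every planted
relation, so recovery, calibration and power are measurable exactly.

Default effect sizes (0.8 per allele / per unit regulator expression at
`n = 300`) are chosen for comfortable detectability, which is what the
generator is for; the acceptance checks use 0.6 at `n = 500`, a regime
where power is high but not saturated.  Counts of trans genes,
regulators and targets may be zero to produce pure-null cohorts for
calibration studies.

What the generator does **not** emulate: realistic recombination maps or
population structure, read-count noise and normalization artifacts
(expression is generated directly on the post-normalization scale),
nonlinear or multi-level regulation, feedback, tissue-to-tissue effect
correlation, and missing data.  Passing tests therefore demonstrate that
the statistical machinery is calibrated and powerful under its own
assumptions — not that those assumptions hold in any particular real
cohort.

# Numerical choices and degenerate inputs

* Ranks use midranks for ties; genotype categories with fewer than two
  samples are kept (no merging) and `k` counts observed categories only.
* A monomorphic SNP draw during simulation is resampled once, then
  errors; a monomorphic SNP during scanning yields rows flagged
  `status = "monomorphic"` rather than silent omission; a monomorphic
  instrument skips its regulator with a logged reason.
* `R²` is defined as 0 when the total sum of squares is 0; residual
  log-ratios are clamped at 0 so LLRs are never negative.
* All order-dependent operations (selection prefixes, instrument argmax,
  network edges) break ties lexicographically by ids, making every
  pipeline output reproducible bit for bit under a fixed seed; the run
  manifest stores MD5 hashes keyed by paths relative to the run
  directory so two runs in different directories compare equal.
* Fisher's exact test is two-sided by default (sum of tables with point
  probability not exceeding the observed), with the conditional-MLE odds
  ratio; infinite odds ratios are written as `"inf"` in TSV output, and
  an empty TF column gives p = 1.
* Replication clustering uses average linkage on the dissimilarity
  `1 - |r|`; genes absent from the replication data are dropped by
  intersection, and the background universe is the discovery/replication
  overlap.

# Problem sizes used by the test suite

The statistical checks run at the scales where their properties are
meaningful yet quick: 1,000-gene single-SNP ensembles at `n = 200` for
null calibration; 20 planted trans pairs among 1,000 genes at `n = 500`
(50 seeds) for FDR honesty; three 20-target regulators plus a 2-target
decoy among 1,000 genes at `n = 500` (10 seeds) for edge recovery and
pruning; 50-target networks at `n = 200–300` (100 seeds) for replication
power and size; and a two-tissue, 150-gene pipeline for end-to-end
determinism.

# Known limitations

Single-SNP instruments only (no multi-instrument or interaction models);
depth-1 causal structure is what the pairwise tests target — regulator
chains appear as overlapping subnetworks rather than hierarchies; the
local-FDR conversion needs ensembles of roughly a hundred statistics and
is conservative for weak signals inside the null bulk; and the
replication test compares correlation distributions, so it detects
preserved co-expression, not preserved direction or topology.
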