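# Synthetic discovery/replication cohort generator.  Emulates the
# statistical structure the analysis assumes: LD-block-structured SNPs at a
# hormone-associated locus, trans-acting SNP -> gene effects, regulator
# genes with their own cis-eQTL instruments, and depth-1 linear
# structural-equation regulator -> target networks that a replication
# cohort shares with attenuated effects.  A truth ledger records every
# planted relation so downstream stages are testable without real data.

.default_tissues <- c("LIV", "SF", "VAF", "AOR", "MAM", "SKLM", "BLOOD")

#' Simulation configuration
#'
#' Bundles and validates the generative parameters of the synthetic cohort.
#' Effect sizes are standardized slopes per allele (genotype coded 0/1/2)
#' or per unit regulator expression; expression is generated on a
#' standardized continuous scale, a surrogate for normalized data.
#'
#' @param n_samples Discovery cohort size.
#' @param n_snps_per_block SNPs per LD block.
#' @param n_blocks Number of LD blocks at the trait-associated locus.
#' @param maf_range Range of minor allele frequencies, within `(0, 0.5]`.
#' @param ld_r Target within-block haplotype correlation: each SNP copies
#'   the latent block haplotype and flips alleles with probability
#'   `(1 - ld_r)/2`.
#' @param n_tissues Number of tissues (expression is generated per tissue
#'   over a shared gene universe).
#' @param tissues Optional tissue ids; defaults to `LIV`, `SF`, `VAF`, ...
#' @param n_genes_per_tissue Size of the gene universe.
#' @param n_trans_genes Genes receiving a trans effect from a locus SNP
#'   (may be 0 for pure-null cohorts).
#' @param trans_effect_size Standardized slope per allele for trans (and
#'   regulator cis) effects.
#' @param n_regulators Network regulator genes (may be 0).  Regulators are
#'   themselves trans-genes of the locus and additionally carry a cis
#'   instrument SNP near the gene.
#' @param targets_per_regulator Targets per regulator; scalar or vector of
#'   length `n_regulators`.
#' @param edge_effect_size Standardized slope of regulator -> target edges.
#' @param noise_sd Independent noise standard deviation.
#' @param replication_attenuation Multiplier in `[0, 1]` applied to edge
#'   effects in the replication cohort.
#' @param replication_n Replication cohort size (default `n_samples`).
#' @param n_null_snps Extra genotyped SNPs with no expression effect and
#'   uniform GWAS p-values.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return An object of class `cortnet_sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_snps_per_block = 5L, n_blocks = 4L,
                       maf_range = c(0.2, 0.45), ld_r = 0.8,
                       n_tissues = 3L, tissues = NULL,
                       n_genes_per_tissue = 300L,
                       n_trans_genes = 10L, trans_effect_size = 0.8,
                       n_regulators = 3L, targets_per_regulator = 10L,
                       edge_effect_size = 0.8, noise_sd = 1,
                       replication_attenuation = 0.8,
                       replication_n = NULL, n_null_snps = 0L, seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_snps_per_block = as.integer(n_snps_per_block),
    n_blocks = as.integer(n_blocks),
    maf_range = as.numeric(maf_range), ld_r = ld_r,
    n_tissues = as.integer(n_tissues),
    tissues = tissues,
    n_genes_per_tissue = as.integer(n_genes_per_tissue),
    n_trans_genes = as.integer(n_trans_genes),
    trans_effect_size = trans_effect_size,
    n_regulators = as.integer(n_regulators),
    targets_per_regulator = as.integer(targets_per_regulator),
    edge_effect_size = edge_effect_size, noise_sd = noise_sd,
    replication_attenuation = replication_attenuation,
    replication_n = if (is.null(replication_n)) NULL else
      as.integer(replication_n),
    n_null_snps = as.integer(n_null_snps),
    seed = as.integer(seed)
  )
  if (is.null(cfg$tissues)) {
    cfg$tissues <- if (cfg$n_tissues <= length(.default_tissues)) {
      .default_tissues[seq_len(cfg$n_tissues)]
    } else {
      c(.default_tissues,
        paste0("T", seq_len(cfg$n_tissues - length(.default_tissues))))
    }
  }
  .validate_sim_config(structure(cfg, class = "cortnet_sim_config"))
}

.validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_samples >= 1, cfg$n_snps_per_block >= 1, cfg$n_blocks >= 1,
    cfg$n_tissues >= 1, cfg$n_genes_per_tissue >= 1,
    cfg$n_trans_genes >= 0, cfg$n_regulators >= 0, cfg$n_null_snps >= 0,
    length(cfg$tissues) == cfg$n_tissues,
    all(cfg$targets_per_regulator >= 1), cfg$noise_sd > 0
  )
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0) {
    stop("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (cfg$ld_r < 0 || cfg$ld_r > 1) stop("ld_r must be in [0, 1]")
  if (cfg$replication_attenuation < 0 || cfg$replication_attenuation > 1) {
    stop("replication_attenuation must be in [0, 1]")
  }
  if (cfg$n_regulators > 0) {
    cfg$targets_per_regulator <-
      rep_len(cfg$targets_per_regulator, cfg$n_regulators)
  } else {
    cfg$targets_per_regulator <- integer(0)
  }
  n_special <- cfg$n_trans_genes + cfg$n_regulators +
    sum(cfg$targets_per_regulator)
  if (n_special > cfg$n_genes_per_tissue) {
    stop("gene universe too small for the planted trans genes, regulators ",
         "and targets")
  }
  cfg
}

# Draw one SNP column; resample once on monomorphism, then error.
.draw_snp <- function(draw_fun, id) {
  g <- draw_fun()
  if (length(unique(g)) < 2) g <- draw_fun()
  if (length(unique(g)) < 2) {
    stop("SNP ", id, " is monomorphic after one resample; ",
         "increase n_samples or maf_range")
  }
  g
}

#' Simulate a discovery cohort with a ground-truth ledger
#'
#' Genotypes are drawn per SNP as the sum of two haplotype alleles; within
#' an LD block every SNP copies a latent block haplotype with per-allele
#' flip probability `(1 - ld_r)/2`.  Per tissue, expression is baseline
#' Gaussian noise; trans genes additionally receive
#' `trans_effect_size * dosage` of their assigned locus SNP; each regulator
#' receives both a trans effect from a locus SNP and a cis effect from its
#' own instrument SNP; each target receives `edge_effect_size * regulator
#' expression` (a depth-1 linear structural-equation model) plus noise.
#' GWAS p-values for locus SNPs are drawn as `10^-U`, `U ~ Uniform(8, 30)`
#' (so they pass genome-wide significance filtering); instrument and null
#' SNPs receive `Uniform(0, 1)` p-values.
#'
#' @param config A [sim_config()].
#' @return An object of class `cortnet_cohort`: a list with `genotypes`
#'   (samples x SNPs dosage matrix), `snp_info`, `expression` (per-tissue
#'   genes x samples matrices), `gene_info`, `gwama` (summary-statistics
#'   table: snp, chr, pos, pval, block), `truth` (the ledger:
#'   `true_trans_pairs`, `true_edges`, `instrument_map`, `snp_block_map`,
#'   `gwama_pvalues`) and `config`.
#' @export
simulate_cohort <- function(config) {
  cfg <- .validate_sim_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  ## ---- genotypes -----------------------------------------------------
  flip <- (1 - cfg$ld_r) / 2
  snp_ids <- character(0); snp_chr <- character(0)
  snp_pos <- integer(0); snp_block <- integer(0)
  geno <- NULL
  for (b in seq_len(cfg$n_blocks)) {
    maf_b <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
    h1 <- stats::rbinom(n, 1, maf_b)
    h2 <- stats::rbinom(n, 1, maf_b)
    for (s in seq_len(cfg$n_snps_per_block)) {
      id <- sprintf("snp_b%d_%02d", b, s)
      g <- .draw_snp(function() {
        f1 <- stats::rbinom(n, 1, flip); f2 <- stats::rbinom(n, 1, flip)
        abs(h1 - f1) + abs(h2 - f2)
      }, id)
      geno <- cbind(geno, g)
      snp_ids <- c(snp_ids, id)
      snp_chr <- c(snp_chr, "14")
      snp_pos <- c(snp_pos, 60e6 + (b - 1) * 4e6 + (s - 1) * 1e4)
      snp_block <- c(snp_block, b)
    }
  }
  block_snps <- snp_ids

  ## ---- gene universe -------------------------------------------------
  G <- cfg$n_genes_per_tissue
  genes <- sprintf("G%04d", seq_len(G))
  tpr <- if (cfg$n_regulators > 0) {
    rep_len(cfg$targets_per_regulator, cfg$n_regulators)
  } else integer(0)
  role <- rep("null", G)
  idx_trans <- seq_len(cfg$n_trans_genes)
  idx_reg <- cfg$n_trans_genes + seq_len(cfg$n_regulators)
  idx_tgt <- cfg$n_trans_genes + cfg$n_regulators + seq_len(sum(tpr))
  role[idx_trans] <- "trans"
  role[idx_reg] <- "regulator"
  role[idx_tgt] <- "target"

  autosomes <- setdiff(as.character(1:22), "14")
  gene_chr <- sample(autosomes, G, replace = TRUE)
  gene_pos <- as.integer(round(stats::runif(G, 1e6, 40e6)))

  # Regulators sit on their own chromosome next to their instrument SNP.
  if (cfg$n_regulators > 0) {
    for (r in seq_len(cfg$n_regulators)) {
      chr_r <- autosomes[(r - 1) %% length(autosomes) + 1]
      gene_chr[idx_reg[r]] <- chr_r
      gene_pos[idx_reg[r]] <- 50e6
      id <- sprintf("snp_cis_%s", genes[idx_reg[r]])
      maf_r <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      g <- .draw_snp(function() stats::rbinom(n, 2, maf_r), id)
      geno <- cbind(geno, g)
      snp_ids <- c(snp_ids, id)
      snp_chr <- c(snp_chr, chr_r)
      snp_pos <- c(snp_pos, as.integer(50e6 + 5e4))
      snp_block <- c(snp_block, NA_integer_)
    }
  }
  if (cfg$n_null_snps > 0) {
    for (j in seq_len(cfg$n_null_snps)) {
      id <- sprintf("snp_null_%03d", j)
      maf_j <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      g <- .draw_snp(function() stats::rbinom(n, 2, maf_j), id)
      geno <- cbind(geno, g)
      snp_ids <- c(snp_ids, id)
      snp_chr <- c(snp_chr, sample(autosomes, 1))
      snp_pos <- c(snp_pos, as.integer(round(stats::runif(1, 1e6, 40e6))))
      snp_block <- c(snp_block, NA_integer_)
    }
  }
  dimnames(geno) <- list(samples, snp_ids)
  snp_info <- data.frame(snp = snp_ids, chr = snp_chr, pos = snp_pos,
                         block = snp_block, stringsAsFactors = FALSE)

  # Trans genes and regulators are assigned locus SNPs round-robin.
  assigned_snp <- rep(NA_character_, G)
  planted <- c(idx_trans, idx_reg)
  if (length(planted) > 0) {
    assigned_snp[planted] <-
      block_snps[(seq_along(planted) - 1) %% length(block_snps) + 1]
  }
  regulator_of <- rep(NA_character_, G)
  if (cfg$n_regulators > 0) {
    regulator_of[idx_tgt] <- rep(genes[idx_reg], times = tpr)
  }
  instrument <- rep(NA_character_, G)
  instrument[idx_reg] <- sprintf("snp_cis_%s", genes[idx_reg])

  gene_info <- data.frame(
    gene = genes, chr = gene_chr, pos = gene_pos, role = role,
    trans_snp = assigned_snp, regulator = regulator_of,
    instrument = instrument, stringsAsFactors = FALSE
  )

  ## ---- expression ----------------------------------------------------
  expression <- vector("list", cfg$n_tissues)
  names(expression) <- cfg$tissues
  for (t in cfg$tissues) {
    M <- matrix(stats::rnorm(G * n, sd = cfg$noise_sd), nrow = G,
                dimnames = list(genes, samples))
    for (i in planted) {
      M[i, ] <- M[i, ] + cfg$trans_effect_size * geno[, assigned_snp[i]]
    }
    for (i in idx_reg) {
      M[i, ] <- M[i, ] + cfg$trans_effect_size * geno[, instrument[i]]
    }
    for (i in idx_tgt) {
      M[i, ] <- M[i, ] +
        cfg$edge_effect_size * M[match(regulator_of[i], genes), ]
    }
    expression[[t]] <- M
  }

  ## ---- truth ledger and summary statistics ---------------------------
  n_locus <- length(block_snps)
  pvals <- numeric(length(snp_ids))
  names(pvals) <- snp_ids
  pvals[block_snps] <- 10^-stats::runif(n_locus, 8, 30)
  others <- setdiff(snp_ids, block_snps)
  pvals[others] <- stats::runif(length(others))

  ttp <- if (length(planted) > 0) {
    expand_tissue <- function(df) {
      do.call(rbind, lapply(cfg$tissues, function(t) cbind(df, tissue = t)))
    }
    expand_tissue(data.frame(snp = assigned_snp[planted],
                             gene = genes[planted],
                             stringsAsFactors = FALSE))
  } else {
    data.frame(snp = character(0), gene = character(0),
               tissue = character(0), stringsAsFactors = FALSE)
  }
  edges <- if (cfg$n_regulators > 0) {
    base <- data.frame(regulator = regulator_of[idx_tgt],
                       target = genes[idx_tgt],
                       sign = sign(cfg$edge_effect_size),
                       stringsAsFactors = FALSE)
    do.call(rbind, lapply(cfg$tissues, function(t) cbind(base, tissue = t)))
  } else {
    data.frame(regulator = character(0), target = character(0),
               sign = numeric(0), tissue = character(0),
               stringsAsFactors = FALSE)
  }
  imap <- stats::setNames(instrument[idx_reg], genes[idx_reg])

  truth <- list(
    snp_block_map = stats::setNames(snp_block, snp_ids),
    true_trans_pairs = ttp[, c("snp", "gene", "tissue")],
    true_edges = edges[, c("regulator", "target", "tissue", "sign")],
    instrument_map = imap,
    gwama_pvalues = pvals,
    genes = genes,
    tissues = cfg$tissues
  )

  gwama <- data.frame(snp = snp_ids, chr = snp_chr, pos = snp_pos,
                      pval = unname(pvals[snp_ids]), block = snp_block,
                      stringsAsFactors = FALSE)

  structure(list(genotypes = geno, snp_info = snp_info,
                 expression = expression, gene_info = gene_info,
                 gwama = gwama, truth = truth, config = cfg),
            class = "cortnet_cohort")
}

#' @export
print.cortnet_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d samples, %d SNPs, %d genes x %d ",
                     "tissue(s)\n  planted: %d trans pairs, %d edges, %d ",
                     "instrumented regulators\n"),
              nrow(x$genotypes), ncol(x$genotypes),
              nrow(x$expression[[1]]), length(x$expression),
              nrow(x$truth$true_trans_pairs) / length(x$expression),
              nrow(x$truth$true_edges) / length(x$expression),
              length(x$truth$instrument_map)))
  invisible(x)
}

#' Simulate a replication cohort sharing the discovery truth
#'
#' Draws new samples over the same gene universe.  Planted regulator ->
#' target edges are reused with effects multiplied by
#' `replication_attenuation`; trans effects are absent because the
#' replication cohort carries no genotypes (expression-only replication,
#' as for public microarray/RNA-seq cohorts).
#'
#' @param truth The `truth` ledger of a [simulate_cohort()] result (or the
#'   cohort itself).
#' @param config The [sim_config()] used for the discovery cohort;
#'   `replication_n` and `replication_attenuation` control this cohort.
#' @return Named list of per-tissue genes x samples expression matrices.
#' @export
simulate_replication <- function(truth, config) {
  if (inherits(truth, "cortnet_cohort")) truth <- truth$truth
  if (is.null(truth$genes) || is.null(truth$true_edges)) {
    stop("truth must come from simulate_cohort()")
  }
  cfg <- .validate_sim_config(config)
  if (cfg$replication_attenuation < 0 || cfg$replication_attenuation > 1) {
    stop("replication_attenuation must be in [0, 1]")
  }
  set.seed(cfg$seed + 1L)
  n <- cfg$replication_n %||% cfg$n_samples
  samples <- sprintf("R%04d", seq_len(n))
  genes <- truth$genes
  att <- cfg$replication_attenuation

  out <- vector("list", length(truth$tissues))
  names(out) <- truth$tissues
  for (t in truth$tissues) {
    M <- matrix(stats::rnorm(length(genes) * n, sd = cfg$noise_sd),
                nrow = length(genes), dimnames = list(genes, samples))
    ed <- truth$true_edges[truth$true_edges$tissue == t, , drop = FALSE]
    for (j in seq_len(nrow(ed))) {
      tgt <- match(ed$target[j], genes)
      reg <- match(ed$regulator[j], genes)
      M[tgt, ] <- M[tgt, ] + att * cfg$edge_effect_size * M[reg, ]
    }
    out[[t]] <- M
  }
  out
}

#' Synthetic glucocorticoid-receptor evidence catalog for a cohort
#'
#' Builds an [evidence_catalog()] whose sets mark the cohort's planted
#' regulators (plus decoy genes), so the evidence-filtering stage can be
#' exercised end to end.  Clearly synthetic: sets are named `*_syn`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param n_decoys Decoy genes added to each database set.
#' @return An `cortnet_evidence_catalog` object.
#' @export
synthetic_gr_catalog <- function(cohort, n_decoys = 10L) {
  stopifnot(inherits(cohort, "cortnet_cohort"))
  set.seed(cohort$config$seed + 2L)
  gi <- cohort$gene_info
  regs <- gi$gene[gi$role == "regulator"]
  nulls <- gi$gene[gi$role == "null"]
  decoys <- if (length(nulls)) {
    sample(nulls, min(n_decoys, length(nulls)))
  } else character(0)
  half <- seq_len(ceiling(length(regs) / 2))
  tissues <- cohort$config$tissues
  murine <- data.frame(
    gene = c(regs, utils::head(decoys, 3)),
    fc = c(rep(2, length(regs)), rep(0.5, min(3, length(decoys)))),
    pval = c(rep(0.001, length(regs)), rep(0.5, min(3, length(decoys)))),
    stringsAsFactors = FALSE
  )
  evidence_catalog(
    tf_db_sets = list(ENCODE_syn = c(regs, decoys),
                      TRANSFAC_syn = c(regs[half], utils::head(decoys, 5)),
                      CHEA_syn = regs[half]),
    chipseq_set = regs,
    dex_de_set = regs,
    murine_dex = murine,
    applicability = gr_applicability(
      tissues,
      adipose = intersect(c("SF", "VAF"), tissues),
      subcutaneous = intersect("SF", tissues))
  )
}

#' Synthetic transcription-factor target sets for a cohort
#'
#' One gene set per planted regulator (`TF_<gene>_syn`), containing its
#' true targets plus decoys, for exercising the enrichment stage.
#'
#' @inheritParams synthetic_gr_catalog
#' @return Named list of gene-id character vectors.
#' @export
synthetic_tf_sets <- function(cohort, n_decoys = 20L) {
  stopifnot(inherits(cohort, "cortnet_cohort"))
  set.seed(cohort$config$seed + 3L)
  gi <- cohort$gene_info
  regs <- gi$gene[gi$role == "regulator"]
  nulls <- gi$gene[gi$role == "null"]
  sets <- lapply(regs, function(r) {
    tg <- gi$gene[!is.na(gi$regulator) & gi$regulator == r]
    dec <- if (length(nulls)) sample(nulls, min(n_decoys, length(nulls)))
           else character(0)
    unique(c(tg, dec))
  })
  stats::setNames(sets, sprintf("TF_%s_syn", regs))
}
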