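# Stage 1: genome-wide-significant SNP filtering, per-tissue SNP x gene
# linkage scan, and selection under a Bayesian global FDR.

#' Filter GWAS summary statistics at a significance threshold
#'
#' Keeps SNPs with p-value strictly below the threshold (default
#' genome-wide significance, 5e-8), preserving input order.
#'
#' @param summary Data frame with at least columns `snp` and `pval`.
#' @param threshold P-value threshold (strict inequality).
#' @return Character vector of SNP ids.
#' @export
filter_gwas_snps <- function(summary, threshold = 5e-8) {
  miss <- setdiff(c("snp", "pval"), names(summary))
  if (length(miss)) {
    stop("summary statistics missing column(s): ", paste(miss, collapse = ", "))
  }
  summary$snp[summary$pval < threshold]
}

#' Scan one tissue: every filtered SNP against every gene
#'
#' For each SNP, computes the secondary linkage LLR against all genes of
#' the tissue (expression supernormalized on the shared samples), the
#' analytic null p-value, and the posterior from empirical local-FDR
#' estimation over the SNP's gene ensemble (or over a pool of SNPs with
#' equal genotype category count when `ensemble = "pooled"`).  SNPs that
#' are monomorphic in the shared samples yield rows flagged
#' `status = "monomorphic"` with missing statistics rather than being
#' silently dropped.
#'
#' @param snps SNP ids to test (e.g. from [filter_gwas_snps()]).
#' @param genotypes Samples x SNPs dosage matrix.
#' @param expr Genes x samples expression matrix.
#' @param tissue Tissue id recorded in the output.
#' @param snp_info Optional data frame (`snp`, `chr`, `pos`, `block`) used
#'   for LD-block and cis/trans annotation.
#' @param gene_info Optional data frame (`gene`, `chr`, `pos`); with
#'   `snp_info` present, a record is labelled cis when the gene lies
#'   within `cis_window` of the SNP.
#' @param cis_window Cis window in base pairs (same chromosome).
#' @param ensemble Posterior pooling scope: per SNP (default) or pooled
#'   across scanned SNPs with the same category count.
#' @param min_stats,lambda Passed to [estimate_posteriors()].
#' @param min_overlap Minimum genotype/expression sample overlap.
#' @return Data frame of association records: `snp`, `gene`, `tissue`,
#'   `block`, `llr`, `pvalue`, `posterior`, `cis`, `status`, `selected`
#'   (initialized `FALSE`).
#' @export
scan_tissue <- function(snps, genotypes, expr, tissue,
                        snp_info = NULL, gene_info = NULL,
                        cis_window = 1e6,
                        ensemble = c("per_snp", "pooled"),
                        min_stats = 100L, lambda = 0.5,
                        min_overlap = 30L) {
  ensemble <- match.arg(ensemble)
  samples <- intersect(colnames(expr), rownames(genotypes))
  if (length(samples) < min_overlap) {
    stop(sprintf("only %d shared samples between genotypes and expression (need >= %d)",
                 length(samples), min_overlap))
  }
  missing_snps <- setdiff(snps, colnames(genotypes))
  if (length(missing_snps)) {
    stop("SNP(s) absent from genotype matrix: ",
         paste(utils::head(missing_snps, 3), collapse = ", "))
  }
  Y <- t(supernormalize_matrix(expr[, samples, drop = FALSE]))
  genes <- colnames(Y)
  n <- length(samples)

  per_snp <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    E <- genotypes[samples, snps[i]]
    k <- length(unique(E))
    rec <- data.frame(snp = snps[i], gene = genes, tissue = tissue,
                      llr = NA_real_, pvalue = NA_real_,
                      posterior = NA_real_, k = k,
                      status = if (k < 2) "monomorphic" else "ok",
                      stringsAsFactors = FALSE)
    if (k >= 2) {
      lm <- .linkage_llr_mat(E, Y)
      rec$llr <- lm$llr
      rec$pvalue <- llr_null_pvalue(lm$llr, n, k)
    }
    per_snp[[i]] <- rec
  }
  records <- do.call(rbind, per_snp)

  ok <- records$status == "ok"
  if (any(ok)) {
    if (ensemble == "per_snp") {
      for (s in unique(records$snp[ok])) {
        idx <- which(ok & records$snp == s)
        fit <- estimate_posteriors(records$llr[idx],
                                   null_model(n, records$k[idx][1], "linkage"),
                                   lambda = lambda, min_stats = min_stats)
        records$posterior[idx] <- fit$posterior
      }
    } else {
      for (kk in unique(records$k[ok])) {
        idx <- which(ok & records$k == kk)
        fit <- estimate_posteriors(records$llr[idx],
                                   null_model(n, kk, "linkage"),
                                   lambda = lambda, min_stats = min_stats)
        records$posterior[idx] <- fit$posterior
      }
    }
  }

  records$block <- NA_integer_
  records$cis <- NA
  if (!is.null(snp_info)) {
    records$block <- snp_info$block[match(records$snp, snp_info$snp)]
    if (!is.null(gene_info)) {
      gi <- match(records$gene, gene_info$gene)
      si <- match(records$snp, snp_info$snp)
      records$cis <- !is.na(gi) & !is.na(si) &
        gene_info$chr[gi] == snp_info$chr[si] &
        abs(gene_info$pos[gi] - snp_info$pos[si]) <= cis_window
    }
  }
  records$k <- NULL
  records$selected <- FALSE
  records[, c("snp", "gene", "tissue", "block", "llr", "pvalue",
              "posterior", "cis", "status", "selected")]
}

# Posterior-descending prefix selection with deterministic tie-breaks.
.select_prefix <- function(records, threshold, tie_cols) {
  ok <- !is.na(records$posterior)
  df <- records[ok, , drop = FALSE]
  if (nrow(df) == 0) {
    return(list(records = df, achieved_fdr = 0, n = 0L))
  }
  args <- c(list(-df$posterior), lapply(tie_cols, function(cn) df[[cn]]))
  ord <- do.call(order, args)
  df <- df[ord, , drop = FALSE]
  cum_fdr <- 1 - cumsum(df$posterior) / seq_len(nrow(df))
  m <- max(0L, which(cum_fdr <= threshold))
  sel <- df[seq_len(m), , drop = FALSE]
  sel$selected <- rep(TRUE, m)
  rownames(sel) <- NULL
  list(records = sel,
       achieved_fdr = if (m > 0) cum_fdr[m] else 0,
       n = m)
}

#' Select associations under a Bayesian global FDR
#'
#' Sorts records by posterior (descending, ties broken lexicographically
#' by SNP then gene id for determinism) and selects the largest prefix
#' whose estimated global FDR, `1 - mean(posterior)`, does not exceed the
#' nominal threshold.  Records with missing posteriors (e.g. monomorphic
#' SNPs) are excluded from selection.
#'
#' @param records Association records from [scan_tissue()] (any data frame
#'   with a `posterior` column and `snp`/`gene` id columns works).
#' @param threshold Nominal global FDR (e.g. 0.15).
#' @return An object of class `cortnet_selection`: `records` (the selected
#'   rows, `selected = TRUE`), `achieved_fdr`, `threshold`, `n_selected`,
#'   `n_tested`.
#' @export
select_by_global_fdr <- function(records, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sel <- .select_prefix(records, threshold, c("snp", "gene"))
  structure(list(records = sel$records, achieved_fdr = sel$achieved_fdr,
                 threshold = threshold, n_selected = sel$n,
                 n_tested = sum(!is.na(records$posterior))),
            class = "cortnet_selection")
}

#' @export
print.cortnet_selection <- function(x, ...) {
  cat(sprintf("Global-FDR selection: %d of %d records at nominal %.0f%% (achieved %.1f%%)\n",
              x$n_selected, x$n_tested, 100 * x$threshold,
              100 * x$achieved_fdr))
  invisible(x)
}

#' Tabulate tissue sharing and LD-block composition of selections
#'
#' @param selections Named list (tissue id -> `cortnet_selection` or a
#'   data frame of selected records carrying `gene`, `tissue`, `block`).
#' @return List with `genes_per_tissue` (unique selected genes per
#'   tissue), `tissue_combinations` (upset-style counts of genes by the
#'   exact set of tissues they appear in) and `block_counts` (association
#'   counts per LD block per tissue).
#' @export
tabulate_sharing <- function(selections) {
  recs <- lapply(names(selections), function(t) {
    s <- selections[[t]]
    df <- if (inherits(s, "cortnet_selection")) s$records else s
    if (nrow(df) == 0) return(NULL)
    df$tissue <- t
    df
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || nrow(recs) == 0) {
    return(list(
      genes_per_tissue = stats::setNames(integer(length(selections)),
                                         names(selections)),
      tissue_combinations = data.frame(combination = character(0),
                                       n_genes = integer(0)),
      block_counts = data.frame(tissue = character(0), block = integer(0),
                                n_associations = integer(0))))
  }
  gpt <- vapply(names(selections), function(t) {
    length(unique(recs$gene[recs$tissue == t]))
  }, integer(1))

  combo <- tapply(recs$tissue, recs$gene, function(ts) {
    paste(sort(unique(ts)), collapse = "+")
  })
  ct <- table(combo)
  combos <- data.frame(combination = names(ct),
                       n_genes = as.integer(ct),
                       stringsAsFactors = FALSE)
  combos <- combos[order(-combos$n_genes, combos$combination), ]
  rownames(combos) <- NULL

  bc <- as.data.frame(table(tissue = recs$tissue,
                            block = addNA(factor(recs$block))),
                      stringsAsFactors = FALSE)
  names(bc)[3] <- "n_associations"
  bc <- bc[bc$n_associations > 0, ]
  rownames(bc) <- NULL

  list(genes_per_tissue = gpt, tissue_combinations = combos,
       block_counts = bc)
}
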