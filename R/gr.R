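# Stage 2: scoring trans-genes for prior evidence of glucocorticoid-
# receptor regulation and selecting instrumented network regulators.

#' Evidence catalog for glucocorticoid-receptor regulation
#'
#' Bundles the four evidence criteria used to score trans-genes:
#' 1. presence in a transcription-factor database (ENCODE/TRANSFAC/CHEA
#'    style; counts once however many databases contain the gene);
#' 2. GR ChIP-seq target in adipocytes;
#' 3. differentially expressed under dexamethasone in adipocytes;
#' 4. murine homolog differentially expressed under dexamethasone
#'    (counted only when `fc > 1` and `pval < 0.05`).
#'
#' The `applicability` map restricts each criterion to the tissues where
#' its evidence is meaningful (perturbation data from adipocytes is only
#' compared with adipose trans-genes, the murine subcutaneous data only
#' with subcutaneous adipose).
#'
#' @param tf_db_sets Named list of gene-id vectors (database evidence).
#' @param chipseq_set Gene-id vector (criterion 2).
#' @param dex_de_set Gene-id vector (criterion 3).
#' @param murine_dex Data frame with columns `gene`, `fc`, `pval`
#'   (criterion 4), or `NULL`.
#' @param applicability Named list `"1"`..`"4"` -> tissue-id vectors, e.g.
#'   from [gr_applicability()].
#' @return An object of class `cortnet_evidence_catalog`.
#' @export
evidence_catalog <- function(tf_db_sets = list(), chipseq_set = character(0),
                             dex_de_set = character(0), murine_dex = NULL,
                             applicability) {
  if (!setequal(names(applicability), c("1", "2", "3", "4"))) {
    stop('applicability must be a named list with criteria "1".."4"')
  }
  if (!is.null(murine_dex)) {
    miss <- setdiff(c("gene", "fc", "pval"), names(murine_dex))
    if (length(miss)) {
      stop("murine_dex missing column(s): ", paste(miss, collapse = ", "))
    }
  }
  structure(list(tf_db_sets = tf_db_sets, chipseq_set = chipseq_set,
                 dex_de_set = dex_de_set, murine_dex = murine_dex,
                 applicability = applicability),
            class = "cortnet_evidence_catalog")
}

#' Default criterion-to-tissue applicability map
#'
#' Criterion 1 (databases) applies everywhere; criteria 2-3 (adipocyte
#' perturbation evidence) only to adipose tissues; criterion 4 (murine
#' subcutaneous data) only to subcutaneous adipose.
#'
#' @param tissues All tissue ids under analysis.
#' @param adipose Adipose tissue ids (criteria 2-3).
#' @param subcutaneous Subcutaneous adipose id(s) (criterion 4).
#' @return Named list suitable for [evidence_catalog()].
#' @export
gr_applicability <- function(tissues, adipose = intersect(c("SF", "VAF"), tissues),
                             subcutaneous = intersect("SF", tissues)) {
  list("1" = tissues, "2" = adipose, "3" = adipose, "4" = subcutaneous)
}

#' Score genes against the GR-evidence criteria
#'
#' Each applicable criterion met adds one point; criterion 1 counts once
#' regardless of how many databases contain the gene.
#'
#' @param genes Gene id(s) to score.
#' @param tissue Tissue id (must appear in the catalog's applicability).
#' @param catalog An [evidence_catalog()].
#' @return Data frame: `gene`, `tissue`, `score` (0-4), `criteria`
#'   (comma-separated criterion ids met).
#' @export
score_gr_evidence <- function(genes, tissue, catalog) {
  stopifnot(inherits(catalog, "cortnet_evidence_catalog"))
  app <- catalog$applicability
  if (!tissue %in% unique(unlist(app))) {
    stop("unknown tissue for this catalog: ", tissue)
  }
  in_db <- if (length(catalog$tf_db_sets)) {
    genes %in% unique(unlist(catalog$tf_db_sets))
  } else rep(FALSE, length(genes))
  c1 <- (tissue %in% app[["1"]]) & in_db
  c2 <- (tissue %in% app[["2"]]) & genes %in% catalog$chipseq_set
  c3 <- (tissue %in% app[["3"]]) & genes %in% catalog$dex_de_set
  c4 <- rep(FALSE, length(genes))
  if (!is.null(catalog$murine_dex) && tissue %in% app[["4"]]) {
    md <- catalog$murine_dex
    hits <- md$gene[md$fc > 1 & md$pval < 0.05]
    c4 <- genes %in% hits
  }
  met <- cbind(c1, c2, c3, c4)
  data.frame(
    gene = genes, tissue = tissue, score = as.integer(rowSums(met)),
    criteria = apply(met, 1L, function(z) paste(which(z), collapse = ",")),
    stringsAsFactors = FALSE
  )
}

#' Retain trans-genes with GR evidence
#'
#' @param trans_genes Data frame with `gene` and `tissue` columns (e.g.
#'   selected trans associations), or a character vector of gene ids
#'   (then `scores` must cover them).
#' @param scores Output of [score_gr_evidence()] covering the candidates.
#' @param min_score Minimum evidence score to retain (default 1).
#' @return Data frame of retained genes ordered by tissue, then score
#'   descending, then gene id.
#' @export
filter_gr_trans_genes <- function(trans_genes, scores, min_score = 1L) {
  if (is.character(trans_genes)) {
    trans_genes <- data.frame(gene = trans_genes,
                              tissue = scores$tissue[match(trans_genes,
                                                           scores$gene)],
                              stringsAsFactors = FALSE)
  }
  key <- paste(trans_genes$gene, trans_genes$tissue)
  skey <- paste(scores$gene, scores$tissue)
  idx <- match(unique(key), skey)
  if (anyNA(idx)) stop("scores missing for some candidate trans-genes")
  out <- scores[idx, , drop = FALSE]
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(out$tissue, -out$score, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Select cis-instrumented regulators among GR trans-genes
#'
#' For each candidate gene, considers SNPs within the cis window of the
#' gene, prices each SNP's primary-linkage LLR against the gene within the
#' SNP's all-gene ensemble, and keeps the SNP with the highest posterior
#' as the gene's instrument if that posterior reaches
#' `posterior_threshold` (ties broken by SNP id).  Genes with no
#' qualifying SNP are dropped with a recorded reason, not an error.
#'
#' @param gr_genes Data frame with `gene` and `tissue` (e.g. from
#'   [filter_gr_trans_genes()]).
#' @param genotypes Samples x SNPs dosage matrix.
#' @param expr Named list of per-tissue genes x samples matrices (or a
#'   single matrix when only one tissue is scored).
#' @param snp_info Data frame `snp`, `chr`, `pos`.
#' @param gene_info Data frame `gene`, `chr`, `pos`.
#' @param posterior_threshold Minimum primary-linkage posterior for a
#'   valid instrument (default 0.75).
#' @param cis_window Cis window in base pairs.
#' @param min_stats,lambda Passed to [estimate_posteriors()].
#' @return Data frame `gene`, `tissue`, `instrument_snp`,
#'   `instrument_posterior`; attribute `"dropped"` is a data frame of
#'   rejected candidates with a `reason` column.
#' @export
select_instrumented_regulators <- function(gr_genes, genotypes, expr,
                                           snp_info, gene_info,
                                           posterior_threshold = 0.75,
                                           cis_window = 1e6,
                                           min_stats = 100L, lambda = 0.5) {
  if (is.matrix(expr)) {
    expr <- stats::setNames(list(expr), unique(gr_genes$tissue)[1])
  }
  kept <- list(); dropped <- list()
  for (t in unique(gr_genes$tissue)) {
    cand <- gr_genes[gr_genes$tissue == t, , drop = FALSE]
    et <- expr[[t]]
    if (is.null(et)) stop("no expression matrix for tissue ", t)
    # All cis SNPs of all candidates, scanned once per tissue.
    cis_of <- lapply(cand$gene, function(g) {
      gi <- gene_info[gene_info$gene == g, , drop = FALSE]
      if (nrow(gi) == 0) return(character(0))
      hit <- snp_info$chr == gi$chr[1] &
        abs(snp_info$pos - gi$pos[1]) <= cis_window
      intersect(snp_info$snp[hit], colnames(genotypes))
    })
    all_cis <- sort(unique(unlist(cis_of)))
    recs <- if (length(all_cis)) {
      scan_tissue(all_cis, genotypes, et, t, snp_info = snp_info,
                  gene_info = gene_info, cis_window = cis_window,
                  min_stats = min_stats, lambda = lambda)
    } else NULL
    for (i in seq_len(nrow(cand))) {
      g <- cand$gene[i]
      snps_g <- cis_of[[i]]
      if (!length(snps_g)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(gene = g, tissue = t, reason = "no_cis_snp",
                     stringsAsFactors = FALSE)
        next
      }
      sub <- recs[recs$gene == g & recs$snp %in% snps_g &
                    recs$status == "ok", , drop = FALSE]
      if (nrow(sub) == 0 || all(is.na(sub$posterior))) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(gene = g, tissue = t, reason = "no_testable_cis_snp",
                     stringsAsFactors = FALSE)
        next
      }
      sub <- sub[order(-sub$posterior, sub$snp), , drop = FALSE]
      if (sub$posterior[1] < posterior_threshold) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(gene = g, tissue = t, reason = "weak_instrument",
                     stringsAsFactors = FALSE)
        next
      }
      kept[[length(kept) + 1L]] <-
        data.frame(gene = g, tissue = t, instrument_snp = sub$snp[1],
                   instrument_posterior = sub$posterior[1],
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(kept)) do.call(rbind, kept) else {
    data.frame(gene = character(0), tissue = character(0),
               instrument_snp = character(0),
               instrument_posterior = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else {
    data.frame(gene = character(0), tissue = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  out
}
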