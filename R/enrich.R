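# Stage 4: Fisher-exact enrichment of known transcription-factor targets
# within network target sets, against a tissue-specific background.

#' Fisher-exact enrichment of a TF target set in a network target set
#'
#' Builds the 2x2 contingency table over a tissue-specific background
#' (network membership x TF-set membership), with the TF set intersected
#' with the background first, and applies Fisher's exact test (two-sided
#' by default: the sum of hypergeometric point probabilities not exceeding
#' that of the observed table).  The odds ratio is the conditional
#' maximum-likelihood estimate; a zero TF column gives p = 1 by
#' convention.
#'
#' @param network_targets Gene ids in the network target set (must lie in
#'   the background; trimmed to it otherwise).
#' @param tf_targets Known TF target gene ids.
#' @param background All genes available in the tissue.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return List with `table` (2x2 matrix: rows in/out of network, columns
#'   in/out of TF set), `odds_ratio` and `pvalue`.
#' @export
fisher_enrichment <- function(network_targets, tf_targets, background,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  if (length(background) == 0) stop("empty background gene set")
  net <- intersect(unique(network_targets), background)
  tf <- intersect(unique(tf_targets), background)
  a <- length(intersect(net, tf))
  b <- length(net) - a
  c_ <- length(tf) - a
  d <- length(background) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(network = c("in", "out"),
                                tf_set = c("in", "out")))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(table = tab, odds_ratio = unname(ft$estimate),
       pvalue = ft$p.value)
}

#' Enrichment of TF sets across networks at several FDR levels
#'
#' One Fisher test per (TF set, network regulator, FDR level); p-values
#' are reported raw (no multiplicity adjustment).
#'
#' @param networks Named list of [build_network()] results; names are the
#'   FDR levels (e.g. `"0.1"`), or any labels.
#' @param tf_sets Named list of TF target gene-id vectors.
#' @param background Tissue-specific background gene ids.
#' @param alternative Passed to [fisher_enrichment()].
#' @return Data frame: `tf`, `regulator`, `fdr_level`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `pvalue`.  Infinite odds ratios are kept as `Inf`
#'   (rendered "inf" in TSV output).
#' @export
enrichment_scan <- function(networks, tf_sets, background,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (inherits(networks, "cortnet_network")) {
    networks <- stats::setNames(list(networks),
                                as.character(networks$fdr_threshold))
  }
  rows <- list()
  for (lev in names(networks)) {
    nw <- networks[[lev]]
    for (reg in nw$regulators) {
      targets <- nw$edges$target[nw$edges$regulator == reg]
      for (tf in names(tf_sets)) {
        fe <- fisher_enrichment(targets, tf_sets[[tf]], background,
                                alternative = alternative)
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, regulator = reg, fdr_level = lev,
          a = fe$table[1, 1], b = fe$table[1, 2],
          c = fe$table[2, 1], d = fe$table[2, 2],
          odds_ratio = fe$odds_ratio, pvalue = fe$pvalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(tf = character(0), regulator = character(0),
                      fdr_level = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), pvalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
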