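# Stage 3: directed causal network reconstruction from instrumented
# regulators, edge selection under a global FDR, and pruning of
# regulators with too few targets.

#' Score all candidate edges from one instrumented regulator
#'
#' Runs the five-test causal suite of the regulator (with its cis
#' instrument) against every other gene in the tissue and combines the
#' posteriors into one causal posterior per candidate edge.
#'
#' @param regulator Regulator gene id (must be a row of `expr`).
#' @param instrument Instrument SNP id (column of `genotypes`).
#' @param genotypes Samples x SNPs dosage matrix.
#' @param expr Genes x samples expression matrix for the tissue.
#' @param tissue Tissue id recorded in the output.
#' @param combine Composite rule, see [combined_causal_posterior()].
#' @param min_stats,lambda Passed to [estimate_posteriors()].
#' @param min_overlap Minimum genotype/expression sample overlap.
#' @return Data frame of candidate edges: `regulator`, `target`, `tissue`,
#'   `posterior`, the five component posteriors and LLRs.
#' @export
score_all_pairs <- function(regulator, instrument, genotypes, expr, tissue,
                            combine = c("default", "conservative"),
                            min_stats = 100L, lambda = 0.5,
                            min_overlap = 30L) {
  combine <- match.arg(combine)
  if (!regulator %in% rownames(expr)) {
    stop("regulator not in expression matrix: ", regulator)
  }
  if (!instrument %in% colnames(genotypes)) {
    stop("instrument not in genotype matrix: ", instrument)
  }
  samples <- intersect(colnames(expr), rownames(genotypes))
  if (length(samples) < min_overlap) {
    stop(sprintf("only %d shared samples (need >= %d)", length(samples),
                 min_overlap))
  }
  E <- genotypes[samples, instrument]
  if (length(unique(E)) < 2) {
    stop("monomorphic instrument: ", instrument,
         " in the overlapping samples")
  }
  targets <- setdiff(rownames(expr), regulator)
  if (!length(targets)) stop("no candidate targets besides the regulator")
  A <- expr[regulator, samples]
  B <- t(expr[targets, samples, drop = FALSE])
  res <- causal_test_suite(E, A, B, min_stats = min_stats, lambda = lambda)
  res$posterior <- combined_causal_posterior(res, method = combine)
  data.frame(regulator = regulator, target = res$target, tissue = tissue,
             posterior = res$posterior,
             res[, c("p_primary", "p_secondary", "p_independence",
                     "p_relevance", "p_controlled",
                     "llr_primary", "llr_secondary", "llr_independence",
                     "llr_relevance", "llr_controlled")],
             stringsAsFactors = FALSE)
}

#' Build a tissue network under a global FDR with regulator pruning
#'
#' Pools candidate edges across the tissue's regulators, selects the
#' largest posterior-descending prefix whose global FDR
#' (`1 - mean(posterior)`) stays within `fdr_threshold`, then drops
#' regulators with fewer than `min_targets` surviving edges (and their
#' edges).  Because pruning can remove above-average edges, the achieved
#' FDR is recomputed after pruning; if it exceeds the threshold the
#' selection is re-run on the remaining regulators' candidates, iterating
#' to a fixed point.  Ties are broken lexicographically by
#' (regulator, target) for determinism.
#'
#' @param edges Candidate edges (rows from [score_all_pairs()], possibly
#'   several regulators concatenated).
#' @param fdr_threshold Nominal global FDR for edges (e.g. 0.10).
#' @param min_targets Minimum surviving targets for a regulator to stay in
#'   the network (default 4).
#' @param scope Pool edges across the tissue (default) or select per
#'   regulator before pooling.
#' @return An object of class `cortnet_network`: `edges`, `regulators`,
#'   `tissue`, `fdr_threshold`, `achieved_fdr`, `dropped_regulators`.
#' @export
build_network <- function(edges, fdr_threshold, min_targets = 4L,
                          scope = c("tissue", "per_regulator")) {
  scope <- match.arg(scope)
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must be in (0, 1)")
  }
  tissue <- unique(edges$tissue)
  if (length(tissue) > 1) stop("build one network per tissue")
  if (length(tissue) == 0) tissue <- NA_character_
  bad <- edges$regulator == edges$target
  if (any(bad)) stop("self-edges are not allowed")

  select_edges <- function(cand) {
    if (scope == "tissue") {
      .select_prefix(cand, fdr_threshold,
                     c("regulator", "target"))$records
    } else {
      do.call(rbind, lapply(split(cand, cand$regulator), function(e) {
        .select_prefix(e, fdr_threshold, c("regulator", "target"))$records
      }))
    }
  }

  cand <- edges
  all_regs <- unique(edges$regulator)
  repeat {
    sel <- select_edges(cand)
    cnt <- table(sel$regulator)
    keep <- names(cnt)[cnt >= min_targets]
    pruned <- sel[sel$regulator %in% keep, , drop = FALSE]
    achieved <- if (nrow(pruned)) 1 - mean(pruned$posterior) else 0
    if (nrow(pruned) == nrow(sel) && achieved <= fdr_threshold) break
    if (!length(keep)) { pruned <- sel[0, , drop = FALSE]; achieved <- 0; break }
    cand <- cand[cand$regulator %in% keep, , drop = FALSE]
  }
  pruned <- pruned[order(pruned$regulator, -pruned$posterior,
                         pruned$target), , drop = FALSE]
  rownames(pruned) <- NULL
  structure(list(edges = pruned,
                 regulators = sort(unique(pruned$regulator)),
                 tissue = tissue, fdr_threshold = fdr_threshold,
                 achieved_fdr = achieved,
                 dropped_regulators = setdiff(all_regs,
                                              unique(pruned$regulator))),
            class = "cortnet_network")
}

#' @export
print.cortnet_network <- function(x, ...) {
  cat(sprintf("Causal network [%s]: %d edges from %d regulator(s) at %.0f%% FDR (achieved %.1f%%)\n",
              x$tissue, nrow(x$edges), length(x$regulators),
              100 * x$fdr_threshold, 100 * x$achieved_fdr))
  if (length(x$dropped_regulators)) {
    cat("  pruned regulators:", paste(x$dropped_regulators, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Per-regulator target counts of a network
#'
#' @param network A [build_network()] result.
#' @return Data frame with columns `tissue`, `fdr`, `total_targets`,
#'   `regulator`, `regulator_targets` (one row per regulator; empty for an
#'   empty network).
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "cortnet_network"))
  if (nrow(network$edges) == 0) {
    return(data.frame(tissue = character(0), fdr = numeric(0),
                      total_targets = integer(0), regulator = character(0),
                      regulator_targets = integer(0),
                      stringsAsFactors = FALSE))
  }
  cnt <- table(network$edges$regulator)
  data.frame(tissue = network$tissue, fdr = network$fdr_threshold,
             total_targets = nrow(network$edges),
             regulator = names(cnt),
             regulator_targets = as.integer(cnt),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a network as GraphML
#'
#' @param network A [build_network()] result.
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "cortnet_network"))
  e <- network$edges
  g <- if (nrow(e)) {
    igraph::graph_from_data_frame(
      e[, c("regulator", "target", "posterior")], directed = TRUE)
  } else {
    igraph::make_empty_graph(directed = TRUE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
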