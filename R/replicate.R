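# Stage 5: co-expression replication of network targets in independent
# expression data, and transfer of the discovery clustering order to
# replication heatmaps.

#' Absolute Pearson correlation matrix for a gene set
#'
#' @param expr Genes x samples expression matrix.
#' @param genes Gene ids; genes absent from the matrix are dropped (their
#'   count is recorded in attribute `"n_dropped"`).
#' @return Symmetric matrix of `|r|` with unit diagonal.
#' @export
abs_corr_matrix <- function(expr, genes) {
  present <- intersect(genes, rownames(expr))
  if (length(present) < 2) {
    stop("fewer than 2 of the requested genes are present in the matrix")
  }
  if (ncol(expr) < 3) stop("need at least 3 samples for correlation")
  m <- abs(stats::cor(t(expr[present, , drop = FALSE])))
  diag(m) <- 1
  attr(m, "n_dropped") <- length(genes) - length(present)
  m
}

.offdiag <- function(m) m[upper.tri(m)]

#' Pooled background correlations from random same-size gene sets
#'
#' For each draw, samples `set_size` genes uniformly without replacement
#' from the background universe and collects the off-diagonal absolute
#' correlations.  Seeded and reproducible.
#'
#' @param expr Genes x samples expression matrix (the replication data).
#' @param set_size Size of each random set (same as the target set).
#' @param n_draws Number of random sets (default 1, one random set per
#'   comparison; more draws stabilize the background).
#' @param seed Integer seed.
#' @param universe Optional gene ids to sample from (default: all rows of
#'   `expr`); use the discovery/replication overlap here.
#' @return Numeric vector of pooled `|r|` values.
#' @export
background_corr_sample <- function(expr, set_size, n_draws = 1L, seed = 1L,
                                   universe = rownames(expr)) {
  universe <- intersect(universe, rownames(expr))
  if (length(universe) < set_size) {
    stop(sprintf("background (%d genes) smaller than set size %d",
                 length(universe), set_size))
  }
  set.seed(seed)
  unlist(lapply(seq_len(n_draws), function(i) {
    g <- sample(universe, set_size)
    .offdiag(abs_corr_matrix(expr, g))
  }))
}

#' Compare target and background correlation distributions
#'
#' Kruskal-Wallis test (midrank tie correction, chi-squared approximation
#' with 1 degree of freedom for two groups) of whether the target-set and
#' random-set absolute correlations follow the same distribution.
#'
#' @param target_corr Off-diagonal `|r|` values among network targets.
#' @param background_corr Pooled `|r|` values from random sets.
#' @return List with `statistic` (the Kruskal-Wallis H) and `pvalue`.
#' @examples
#' compare_distributions(c(1, 2, 3), c(4, 5, 6))  # H = 3.857, p = 0.0495
#' @export
compare_distributions <- function(target_corr, background_corr) {
  if (length(target_corr) == 0 || length(background_corr) == 0) {
    stop("both correlation samples must be nonempty")
  }
  kw <- stats::kruskal.test(list(target_corr, background_corr))
  list(statistic = unname(kw$statistic), pvalue = kw$p.value)
}

#' Transfer the discovery clustering order to a replication matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - |r|` of the discovery matrix; the resulting leaf order permutes
#' both matrices for side-by-side heatmap rendering.
#'
#' @param discovery_corr Absolute-correlation matrix from the discovery
#'   data.
#' @param replication_corr Absolute-correlation matrix from the
#'   replication data (genes are intersected first).
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return List with `leaf_order` (gene ids in dendrogram order),
#'   `discovery` and `replication` (both matrices reordered), and
#'   `hclust` (the discovery tree).
#' @export
transfer_cluster_order <- function(discovery_corr, replication_corr,
                                   method = "average") {
  genes <- intersect(rownames(discovery_corr), rownames(replication_corr))
  if (length(genes) < 2) stop("fewer than 2 shared genes between matrices")
  d <- discovery_corr[genes, genes]
  r <- replication_corr[genes, genes]
  hc <- stats::hclust(stats::as.dist(1 - d), method = method)
  lo <- genes[hc$order]
  list(leaf_order = lo, discovery = d[lo, lo], replication = r[lo, lo],
       hclust = hc)
}

#' Replicate one regulator's network in an independent dataset
#'
#' Computes the distribution of absolute correlations among the network
#' targets in the replication expression data, compares it with random
#' same-size gene sets drawn from the discovery/replication gene overlap
#' via the Kruskal-Wallis test, and transfers the discovery clustering
#' order onto the replication correlation matrix.
#'
#' @param targets Target gene ids of the regulator's network.
#' @param discovery_expr Genes x samples discovery expression matrix.
#' @param replication_expr Genes x samples replication expression matrix.
#' @param regulator,dataset Ids recorded in the result.
#' @param n_draws,seed Passed to [background_corr_sample()].
#' @return An object of class `cortnet_replication`: `regulator`,
#'   `dataset`, `n_targets`, `kw_statistic`, `pvalue`, `target_corr`,
#'   `background_corr`, `leaf_order`, `discovery_corr`,
#'   `replication_corr`.
#' @export
replicate_network <- function(targets, discovery_expr, replication_expr,
                              regulator = NA_character_,
                              dataset = NA_character_,
                              n_draws = 1L, seed = 1L) {
  universe <- intersect(rownames(discovery_expr), rownames(replication_expr))
  present <- intersect(targets, universe)
  if (length(present) < 2) {
    stop("fewer than 2 network targets present in both datasets")
  }
  rc <- abs_corr_matrix(replication_expr, present)
  target_corr <- .offdiag(rc)
  background_corr <- background_corr_sample(
    replication_expr, set_size = length(present), n_draws = n_draws,
    seed = seed, universe = universe)
  kw <- compare_distributions(target_corr, background_corr)
  dc <- abs_corr_matrix(discovery_expr, present)
  ord <- transfer_cluster_order(dc, rc)
  structure(list(regulator = regulator, dataset = dataset,
                 n_targets = length(present),
                 kw_statistic = kw$statistic, pvalue = kw$pvalue,
                 target_corr = target_corr,
                 background_corr = background_corr,
                 leaf_order = ord$leaf_order,
                 discovery_corr = ord$discovery,
                 replication_corr = ord$replication),
            class = "cortnet_replication")
}

#' @export
print.cortnet_replication <- function(x, ...) {
  cat(sprintf("Replication of %s in %s: %d targets, KW H = %.2f, p = %.3g\n",
              x$regulator, x$dataset, x$n_targets, x$kw_statistic,
              x$pvalue))
  invisible(x)
}

#' Heatmap pair for a replication result
#'
#' Renders discovery and replication correlation matrices (both in the
#' discovery leaf order) with pheatmap, when available.
#'
#' @param rep A [replicate_network()] result.
#' @param path Optional PNG path; when `NULL`, plots to the active device.
#' @export
plot_replication_heatmap <- function(rep, path = NULL) {
  stopifnot(inherits(rep, "cortnet_replication"))
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("pheatmap is required for heatmap rendering")
  }
  if (!is.null(path)) grDevices::png(path, width = 1400, height = 700)
  on.exit(if (!is.null(path)) grDevices::dev.off())
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old), add = TRUE)
  pheatmap::pheatmap(rep$discovery_corr, cluster_rows = FALSE,
                     cluster_cols = FALSE, main = "discovery",
                     silent = FALSE)
  pheatmap::pheatmap(rep$replication_corr, cluster_rows = FALSE,
                     cluster_cols = FALSE, main = rep$dataset,
                     silent = FALSE)
  invisible(rep)
}
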