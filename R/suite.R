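# The five-test pairwise causal inference suite with a genotype instrument.

#' Pairwise causal test suite with a genetic instrument
#'
#' Given a genotype instrument `E` (cis-eQTL of the regulator), the
#' regulator expression `A`, and one or more candidate target genes `B`,
#' computes the five likelihood-ratio tests of instrument-based pairwise
#' causal inference and converts each to a posterior probability by
#' empirical local-FDR estimation over the gene ensemble:
#'
#' * **primary** - linkage `E -> A` (the instrument is a cis-eQTL of A);
#' * **secondary** - linkage `E -> B`;
#' * **independence** - `B` independent of `E` given `A`; the reported
#'   posterior is the probability of this *null* (the local FDR itself),
#'   so it is high when `A` fully mediates the instrument's effect on `B`;
#' * **relevance** - `B` associated with `E` and/or `A` versus isolated;
#' * **controlled** - `A` adds explanatory power for `B` beyond `E`
#'   (`E -> A -> B` versus independent `E -> A` and `E -> B`).
#'
#' Expression inputs are supernormalized internally unless
#' `normalize = FALSE`.  Posteriors for the secondary, independence,
#' relevance and controlled tests are estimated over the ensemble of
#' candidate genes (per-instrument-across-all-genes pooling); the primary
#' posterior is obtained by evaluating the primary LLR within the
#' secondary-test ensemble, which shares its null.
#'
#' @param E Genotype vector (allele dosages, treated as categories).
#' @param A Regulator expression vector.
#' @param B Candidate target expression: a vector, or a samples-by-genes
#'   matrix / genes-by-samples matrix with `genes_in_rows = TRUE`.
#' @param genes_in_rows If `B` is a matrix, set `TRUE` when genes are rows.
#' @param normalize Supernormalize `A` and the columns of `B` first.
#' @param min_stats Minimum ensemble size for posterior estimation.
#' @param lambda Storey pi0 tuning parameter, see [estimate_posteriors()].
#' @return A data frame with one row per candidate gene: `target`, the five
#'   LLRs (`llr_primary` ... `llr_controlled`), the five posteriors
#'   (`p_primary` ... `p_controlled`), and `posterior`, the combined causal
#'   posterior from [combined_causal_posterior()].
#' @export
causal_test_suite <- function(E, A, B, genes_in_rows = FALSE,
                              normalize = TRUE, min_stats = 100L,
                              lambda = 0.5) {
  if (is.null(dim(B))) {
    B <- matrix(B, ncol = 1L, dimnames = list(NULL, "B"))
  } else if (genes_in_rows) {
    B <- t(B)
  }
  if (normalize) {
    A <- supernormalize(A)
    B <- apply(B, 2L, supernormalize)
  }
  st <- .suite_llr_mat(E, A, B)
  n <- st$n; k <- st$k
  G <- ncol(B)

  post_for <- function(llr, test, extra = numeric()) {
    ens <- c(llr, extra)
    fit <- estimate_posteriors(ens, null_model(n, k, test),
                               lambda = lambda, min_stats = min_stats)
    fit$posterior
  }

  # Secondary ensemble also prices the primary statistic (same null family).
  p2_all <- post_for(st$llr2, "linkage", extra = st$llr1)
  p2 <- p2_all[seq_len(G)]
  p1 <- p2_all[G + 1L]
  p3 <- 1 - post_for(st$llr3, "independence")   # posterior of the null
  p4 <- post_for(st$llr4, "relevance")
  p5 <- post_for(st$llr5, "controlled")

  res <- data.frame(
    target = colnames(B) %||% paste0("B", seq_len(G)),
    llr_primary = st$llr1, llr_secondary = st$llr2,
    llr_independence = st$llr3, llr_relevance = st$llr4,
    llr_controlled = st$llr5,
    p_primary = p1, p_secondary = p2, p_independence = p3,
    p_relevance = p4, p_controlled = p5,
    stringsAsFactors = FALSE
  )
  res$posterior <- combined_causal_posterior(res)
  rownames(res) <- NULL
  res
}

#' Combine the five test posteriors into one causal posterior
#'
#' The default composite is `P(A -> B) = (P_secondary * P_controlled +
#' P_relevance) / 2`, which trades confounding robustness for power and
#' tolerates hidden confounders acting on both genes.  The conservative
#' alternative `P_secondary * P_independence` additionally requires the
#' instrument's effect on the target to be fully mediated by the regulator.
#'
#' @param tests A data frame (or list) carrying `p_secondary`,
#'   `p_independence`, `p_relevance`, `p_controlled` (as returned by
#'   [causal_test_suite()]).
#' @param method `"default"` or `"conservative"`.
#' @return Numeric vector of combined posteriors in `[0, 1]`.
#' @examples
#' combined_causal_posterior(data.frame(
#'   p_secondary = 0.8, p_independence = 0.9,
#'   p_relevance = 0.6, p_controlled = 0.5))  # (0.8*0.5 + 0.6)/2 = 0.5
#' @export
combined_causal_posterior <- function(tests,
                                      method = c("default", "conservative")) {
  method <- match.arg(method)
  need <- c("p_secondary", "p_relevance", "p_controlled", "p_independence")
  miss <- setdiff(if (method == "default") need[1:3] else need[c(1, 4)],
                  names(tests))
  if (length(miss)) {
    stop("missing component test posterior(s): ", paste(miss, collapse = ", "))
  }
  p <- if (method == "default") {
    (tests$p_secondary * tests$p_controlled + tests$p_relevance) / 2
  } else {
    tests$p_secondary * tests$p_independence
  }
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("component posteriors outside [0, 1]")
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
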