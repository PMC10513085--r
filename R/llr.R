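# Likelihood-ratio statistics for SNP-gene association and pairwise causal
# inference, with analytic null distributions.  All tests compare nested
# Gaussian models by the ratio of maximum-likelihood residual variances:
# LLR = (n/2) * log(var_null / var_alt) >= 0.  Under the null hypothesis the
# realized variance-reduction fraction 1 - exp(-2*LLR/n) follows a
# Beta(d1/2, d2/2) distribution, where d1 is the number of extra parameters
# in the alternative model and d2 its residual degrees of freedom.

.as_genotype_factor <- function(E) {
  if (anyNA(E)) stop("missing genotypes not allowed; apply listwise deletion first")
  factor(E)
}

#' Linkage likelihood-ratio statistic for a SNP-gene pair
#'
#' Tests association between a categorical genotype `E` (allele dosages
#' 0/1/2) and an expression vector `y` by categorical regression: the
#' alternative model gives each genotype group its own mean.  The statistic
#' is `LLR = -(n/2) * ln(1 - R^2)` with `R^2` the between-group over total
#' sum of squares; `R^2` is defined as 0 when the total sum of squares is 0.
#' The same statistic serves the primary (instrument to regulator) and
#' secondary (instrument to candidate gene) linkage tests.
#'
#' @param E Genotype vector; values are treated as categories, `k` counts
#'   the distinct observed categories.
#' @param y Numeric expression vector of the same length.
#' @return A single nonnegative number.
#' @examples
#' linkage_llr(c(0, 0, 1, 1, 2, 2), c(1, 2, 2, 3, 3, 4))
#' @export
linkage_llr <- function(E, y) {
  if (length(E) != length(y)) stop("genotype and expression lengths differ")
  f <- .as_genotype_factor(E)
  if (nlevels(f) < 2) stop("monomorphic instrument: k < 2 genotype categories")
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  gm <- tapply(y, f, mean)
  nj <- tabulate(f)
  r2 <- sum(nj * (gm - mean(y))^2) / sst
  max(0, -(n / 2) * log1p(-min(r2, 1)))
}

# Beta shape parameters of the null distribution of 1 - exp(-2*LLR/n) for
# each member of the test suite, given n samples and k genotype categories.
# primary/secondary: k-1 group means beyond the grand mean, n-k residual df.
# independence: B ~ A (2 params) vs B ~ E + A (k+1 params).
# relevance: B ~ 1 vs B ~ E + A.
# controlled: B ~ E vs B ~ E + A.
.llr_beta_shapes <- function(n, k,
                             test = c("linkage", "independence",
                                      "relevance", "controlled")) {
  test <- match.arg(test)
  switch(test,
    linkage      = c(d1 = (k - 1) / 2, d2 = (n - k) / 2),
    independence = c(d1 = (k - 1) / 2, d2 = (n - k - 1) / 2),
    relevance    = c(d1 = k / 2,       d2 = (n - k - 1) / 2),
    controlled   = c(d1 = 1 / 2,       d2 = (n - k - 1) / 2)
  )
}

#' Null model for a family of LLR statistics
#'
#' Describes the analytic null of one test of the suite for a fixed sample
#' size and genotype category count, used for p-values and for the null
#' density entering the empirical local-FDR posterior conversion.
#'
#' @param n Sample count.
#' @param k Number of distinct observed genotype categories (>= 2).
#' @param test Which member of the test suite the statistics come from.
#' @return An object of class `cortnet_null` with fields `n`, `k`, `test`,
#'   and the Beta shape parameters `d1`, `d2`.
#' @export
null_model <- function(n, k, test = c("linkage", "independence",
                                      "relevance", "controlled")) {
  test <- match.arg(test)
  if (k < 2) stop("monomorphic instrument: k < 2 genotype categories")
  if (n <= k + (test != "linkage")) stop("insufficient degrees of freedom: n <= k")
  sh <- .llr_beta_shapes(n, k, test)
  structure(list(n = n, k = k, test = test,
                 d1 = unname(sh["d1"]), d2 = unname(sh["d2"]), pi0 = NA_real_),
            class = "cortnet_null")
}

#' @export
print.cortnet_null <- function(x, ...) {
  cat(sprintf("LLR null model [%s]: n = %d, k = %d, Beta(%.1f, %.1f)%s\n",
              x$test, x$n, x$k, x$d1, x$d2,
              if (is.na(x$pi0)) "" else sprintf(", pi0 = %.3f", x$pi0)))
  invisible(x)
}

# Vectorized p-value under a cortnet_null.
.llr_pvalue <- function(llr, null) {
  x <- -expm1(-2 * llr / null$n)
  stats::pbeta(x, null$d1, null$d2, lower.tail = FALSE)
}

#' Analytic null p-value for a linkage LLR
#'
#' Under the null hypothesis of no association, the fraction of variance
#' explained `R^2 = 1 - exp(-2 LLR / n)` follows a
#' `Beta((k-1)/2, (n-k)/2)` distribution; the p-value is its upper tail at
#' the observed `R^2`.
#'
#' @param llr Nonnegative LLR statistic (vectorized).
#' @param n Sample count.
#' @param k Number of distinct observed genotype categories.
#' @return P-value(s) in `[0, 1]`.
#' @examples
#' llr_null_pvalue(0, n = 100, k = 3)                  # 1
#' llr_null_pvalue(-2 * log(0.75), n = 4, k = 2)       # 0.5
#' @export
llr_null_pvalue <- function(llr, n, k) {
  if (any(llr < 0)) stop("llr must be nonnegative")
  if (n <= k) stop("insufficient degrees of freedom: n <= k")
  .llr_pvalue(llr, null_model(n, k, "linkage"))
}

# ---- Vectorized statistics across a gene ensemble -------------------------

# Linkage LLRs of one genotype vector against every column of Y (n x G).
# Returns list(llr, k).
.linkage_llr_mat <- function(E, Y) {
  f <- .as_genotype_factor(E)
  k <- nlevels(f)
  if (k < 2) stop("monomorphic instrument: k < 2 genotype categories")
  n <- nrow(Y)
  if (length(E) != n) stop("genotype and expression lengths differ")
  Z <- stats::model.matrix(~ 0 + f)
  nj <- colSums(Z)
  mu <- crossprod(Z, Y) / nj                      # k x G group means
  ybar <- colMeans(Y)
  sst <- colSums(Y^2) - n * ybar^2
  ssb <- colSums(mu^2 * nj) - n * ybar^2
  r2 <- ifelse(sst > 0, pmin(ssb / sst, 1), 0)
  list(llr = pmax(0, -(n / 2) * log1p(-r2)), k = k, n = n)
}

# Full five-test LLRs of (E, A) against every column of B (n x G).
# A must not be a column of B (exclude the regulator upstream).
.suite_llr_mat <- function(E, A, B) {
  f <- .as_genotype_factor(E)
  k <- nlevels(f)
  if (k < 2) stop("monomorphic instrument: k < 2 genotype categories")
  n <- nrow(B)
  if (length(E) != n || length(A) != n) stop("input lengths differ")
  if (n <= k + 1) stop("insufficient degrees of freedom: n <= k + 1")
  Z <- stats::model.matrix(~ 0 + f)
  nj <- colSums(Z)

  # Sums of squares for B columns
  muB <- crossprod(Z, B) / nj
  bbar <- colMeans(B)
  sstB <- colSums(B^2) - n * bbar^2
  ssbB <- colSums(muB^2 * nj) - n * bbar^2
  sswB <- pmax(sstB - ssbB, 0)

  # Regulator A: group-centred and grand-centred versions
  muA <- tapply(A, f, mean)
  Ac <- A - muA[as.integer(f)]                    # within-group centred
  A0 <- A - mean(A)
  saw <- sum(Ac^2)
  sa0 <- sum(A0^2)

  # Cross products (group-centring of B is absorbed because sum(Ac) = 0
  # within each genotype group)
  crossW <- as.vector(crossprod(B, Ac))
  cross0 <- as.vector(crossprod(B, A0))

  rss_full <- pmax(sswB - if (saw > 0) crossW^2 / saw else 0, 0)
  rss_onA  <- pmax(sstB - if (sa0 > 0) cross0^2 / sa0 else 0, 0)

  safe_ratio_llr <- function(num, den) {
    # (n/2) log(num/den), guarded for zero residuals
    out <- rep(Inf, length(den))
    ok <- den > 0
    out[ok] <- pmax(0, (n / 2) * (log(num[ok]) - log(den[ok])))
    out[num == 0 & !ok] <- 0
    out
  }

  llr2 <- pmax(0, -(n / 2) * log1p(-ifelse(sstB > 0, pmin(ssbB / sstB, 1), 0)))
  llr3 <- safe_ratio_llr(rss_onA, rss_full)
  llr4 <- safe_ratio_llr(sstB, rss_full)
  llr5 <- safe_ratio_llr(sswB, rss_full)

  # Primary linkage of the regulator itself
  sstA <- sum(A0^2)
  ssbA <- sum(nj * (muA - mean(A))^2)
  r2A <- if (sstA > 0) min(ssbA / sstA, 1) else 0
  llr1 <- max(0, -(n / 2) * log1p(-r2A))

  list(llr1 = llr1, llr2 = llr2, llr3 = llr3, llr4 = llr4, llr5 = llr5,
       n = n, k = k)
}
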