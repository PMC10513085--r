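# Conversion of LLR statistics to posterior probabilities by empirical
# estimation of the local false discovery rate over a gene ensemble.

# Histogram bin edges on the null-CDF (p-value) scale: decile bins over
# the null bulk and geometrically refined bins in the tail down to a tenth
# of 1/m, so every bin has a known null mass and the resolution
# concentrates where alternatives separate from the null.
.pvalue_breaks <- function(m) {
  tail_lo <- floor(2 * (log10(m) + 1)) / 2
  p_edges <- c(1, seq(0.9, 0.1, by = -0.1), 10^-seq(1.5, tail_lo, by = 0.5), 0)
  unique(p_edges)
}

#' Convert LLR statistics to posteriors via empirical local FDR
#'
#' Implements the posterior conversion `P(H_alt | LLR)` for an ensemble of
#' test statistics sharing one null model.  The local false discovery rate
#' at statistic `L` is `pi0 * f0(L) / f(L)`; both the analytic null
#' density `f0` and the empirical mixture density `f` are averaged over
#' histogram bins laid out on the null-CDF scale (decile bins across the
#' null bulk, geometrically refined bins in the tail), so each bin has a
#' known null mass and the observed-to-null mass ratio estimates `f/f0`
#' directly.  The ratio is made monotone nondecreasing in LLR by
#' null-mass-weighted isotonic regression (a binned Grenander-type
#' monotone density-ratio estimate), giving posteriors `1 - pi0/ratio`
#' clamped to `[0, 1]`, nondecreasing in LLR, with exact ties receiving
#' equal posteriors.
#'
#' Estimation is ensemble-based: at least `min_stats` statistics are
#' required.  Pool statistics across instruments with the same `(n, k)`
#' when a single ensemble is too small.
#'
#' @param llr Numeric vector of nonnegative LLR statistics (one ensemble,
#'   e.g. one instrument SNP tested against all genes of a tissue).
#' @param null A [null_model()] shared by the ensemble.
#' @param lambda Storey tuning parameter for the p-value-based
#'   null-proportion estimate `pi0 = #\{p > lambda\} / ((1 - lambda) m)`,
#'   clamped to `[0, 1]`.
#' @param min_stats Minimum ensemble size.
#' @param pi0_method `"ratio"` (default) anchors the null proportion to
#'   the monotone density ratio evaluated at the null's median LLR
#'   (central matching: the region where the mixture is null-dominated and
#'   the true local FDR is 1), so the local FDR estimate is exactly 1
#'   through the null bulk instead of inheriting the noise of an
#'   independent estimate; `"storey"` uses the p-value estimate.
#' @return A data frame with columns `llr`, `pvalue`, `lfdr`, `posterior`
#'   (rows in input order) and attribute `pi0`.
#' @export
estimate_posteriors <- function(llr, null, lambda = 0.5, min_stats = 100L,
                                pi0_method = c("ratio", "storey")) {
  pi0_method <- match.arg(pi0_method)
  m <- length(llr)
  if (m < min_stats) {
    stop(sprintf(paste0("only %d statistics; posterior estimation is ",
                        "ensemble-based (needs >= %d) - pool statistics ",
                        "across instruments with equal (n, k)"),
                 m, min_stats))
  }
  if (any(llr < 0)) stop("llr must be nonnegative")
  pvalue <- .llr_pvalue(llr, null)
  pi0 <- min(1, sum(pvalue > lambda) / ((1 - lambda) * m))

  if (diff(range(llr)) == 0) {
    post <- rep(max(0, 1 - pi0), m)
    out <- data.frame(llr = llr, pvalue = pvalue,
                      lfdr = 1 - post, posterior = post)
    attr(out, "pi0") <- pi0
    return(out)
  }

  # Bins on the null-CDF scale, ordered by increasing LLR (decreasing p)
  br_p <- .pvalue_breaks(m)                      # decreasing p edges
  br_inc <- rev(br_p)                            # increasing for findInterval
  nb <- length(br_inc) - 1L
  bin_p <- findInterval(pvalue, br_inc, rightmost.closed = TRUE,
                        all.inside = TRUE)
  bin <- nb + 1L - bin_p                         # increasing-LLR order
  obs <- tabulate(bin, nbins = nb) / m           # observed mass per bin
  exp0 <- rev(diff(br_inc))                      # exact null mass per bin

  # Mixture-to-null density ratio per bin, made monotone nondecreasing in
  # LLR by null-mass-weighted isotonic regression; lfdr = pi0 / ratio.
  q <- pmax(exp0, .Machine$double.xmin)
  ratio <- pmin(obs / q, 1e12)
  ratio_iso <- .pava(ratio, q)
  if (pi0_method == "ratio") {
    # central matching under the zero assumption: the mixture is taken as
    # purely null throughout the null's central 90% mass, so the ratio
    # level there calibrates pi0 and the local FDR is pinned to 1 across
    # the null bulk; only statistics beyond it can earn posterior > 0
    anchor <- which(cumsum(exp0) >= 0.9 - 1e-9)[1]
    pi0 <- min(1, ratio_iso[anchor])
  }
  lfdr_bin <- pmin(1, pi0 / pmax(ratio_iso, .Machine$double.xmin))
  post <- 1 - lfdr_bin[bin]
  post <- pmin(1, pmax(0, post))

  out <- data.frame(llr = llr, pvalue = pvalue,
                    lfdr = 1 - post, posterior = post)
  attr(out, "pi0") <- pi0
  out
}

# Weighted pool-adjacent-violators algorithm (nondecreasing fit).
.pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- rep(1L, n)  # block sizes
  i <- 1L
  nblock <- n
  # iterative merging on vectors
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nblock) {
      if (val[i] > val[i + 1L]) {
        tw <- wt[i] + wt[i + 1L]
        val[i] <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) /
          if (tw > 0) tw else 1
        wt[i] <- tw
        idx[i] <- idx[i] + idx[i + 1L]
        val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; idx <- idx[-(i + 1L)]
        nblock <- nblock - 1L
        merged <- TRUE
        if (i > 1L) i <- i - 1L
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  rep(val, times = idx)
}
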