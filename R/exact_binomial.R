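#' Exact probability of a pool allele-frequency difference
#'
#' The scan's per-SNP test. Given alt-allele counts `k_u` of `n_u` reads in
#' the unicellular-enriched pool and `k_m` of `n_m` in the
#' multicellular-enriched pool, the null model takes the pooled frequency
#' `p_hat = (k_u + k_m) / (n_u + n_m)` as given and asks how probable a
#' frequency difference at least as large as the observed one is when both
#' pools are resequenced independently: with `K_u ~ Binomial(n_u, p_hat)` and
#' `K_m ~ Binomial(n_m, p_hat)` independent,
#' \deqn{p = P(|K_u n_m - K_m n_u| \ge |k_u n_m - k_m n_u|).}
#' Conditioning on the observed overall frequency (rather than on an expected
#' 1:1 segregation) makes the test insensitive to alleles that drifted in
#' frequency while the pools were grown out: only sampling error or selection
#' during pool separation can produce a difference between the pools.
#'
#' Frequency differences are compared as cross-multiplied integers, so ties
#' are exact and the observed outcome always counts (`p > 0`, inclusive
#' tail). The computation enumerates one pool's outcomes and uses the
#' binomial CDF for the other, which equals the full double enumeration to
#' floating-point accuracy.
#'
#' @param k_u,n_u alt count and total depth in the unicellular pool.
#' @param k_m,n_m alt count and total depth in the multicellular pool.
#'   All four arguments are recycled to a common length.
#' @param sided `"two"` (default): tail on the magnitude of the difference;
#'   `"greater"`: one-sided tail on `k_m/n_m - k_u/n_u` at least as large as
#'   observed.
#' @param conditional if `TRUE`, condition on the total alt count
#'   `k_u + k_m` (a Fisher-style hypergeometric null) instead of the two
#'   independent binomials; provided for sensitivity analysis.
#' @return Numeric vector of exact tail probabilities in `(0, 1]`; `NA` where
#'   a pool has zero depth.
#' @seealso [log_odds()] for the scan score, [bsa_scan()] for the full scan.
#' @export
#' @examples
#' exact_difference_probability(5, 10, 5, 10)   # no difference -> 1
#' exact_difference_probability(1, 10, 9, 10)   # strong difference
exact_difference_probability <- function(k_u, n_u, k_m, n_m,
                                         sided = c("two", "greater"),
                                         conditional = FALSE) {
  sided <- match.arg(sided)
  nn <- max(length(k_u), length(n_u), length(k_m), length(n_m))
  k_u <- rep_len(k_u, nn); n_u <- rep_len(n_u, nn)
  k_m <- rep_len(k_m, nn); n_m <- rep_len(n_m, nn)
  if (any(k_u > n_u | k_m > n_m | k_u < 0 | k_m < 0, na.rm = TRUE))
    stop("allele counts must satisfy 0 <= k <= n in each pool")
  vapply(seq_len(nn), function(i) {
    if (n_u[i] < 1 || n_m[i] < 1) return(NA_real_)
    if (conditional)
      exact_diff_p_conditional(k_u[i], n_u[i], k_m[i], n_m[i], sided)
    else
      exact_diff_p_binomial(k_u[i], n_u[i], k_m[i], n_m[i], sided)
  }, numeric(1))
}

# Two independent binomials at the pooled MLE; O(n_u) with the CDF over the
# other pool. All difference comparisons are on exact integers
# (cross-multiplied), so tie handling is platform-independent.
exact_diff_p_binomial <- function(k_u, n_u, k_m, n_m, sided) {
  phat <- (k_u + k_m) / (n_u + n_m)
  ku_all <- 0:n_u
  a <- ku_all * n_m
  wu <- dbinom(ku_all, n_u, phat)
  if (sided == "two") {
    d0 <- abs(k_m * n_u - k_u * n_m)
    if (d0 == 0) return(1)  # every outcome is at least as extreme
    # strictly inside band: a - d0 < k_m' * n_u < a + d0
    lo <- floor((a - d0) / n_u) + 1
    hi <- ceiling((a + d0) / n_u) - 1
    outside <- ifelse(hi < lo, 1,
                      pbinom(lo - 1, n_m, phat) +
                        pbinom(hi, n_m, phat, lower.tail = FALSE))
  } else {
    t0 <- k_m * n_u - k_u * n_m
    # qualifying: k_m' * n_u >= t0 + a
    lo <- ceiling((t0 + a) / n_u)
    outside <- pbinom(lo - 1, n_m, phat, lower.tail = FALSE)
  }
  min(1, sum(wu * outside))
}

# Fisher-style variant: condition on s = k_u + k_m; K_u | s is hypergeometric.
exact_diff_p_conditional <- function(k_u, n_u, k_m, n_m, sided) {
  s <- k_u + k_m
  ku_all <- max(0, s - n_m):min(s, n_u)
  w <- dhyper(ku_all, n_u, n_m, s)
  t_all <- (s - ku_all) * n_u - ku_all * n_m
  t0 <- k_m * n_u - k_u * n_m
  keep <- if (sided == "two") abs(t_all) >= abs(t0) else t_all >= t0
  if (all(keep)) return(1)
  min(1, sum(w[keep]))
}

#' Log-odds scan score from an exact tail probability
#'
#' Transforms a tail probability into the score plotted along the genome:
#' `log10((1 - p) / p)`, the base-10 log odds that the observed pool
#' difference is *not* a chance fluctuation. Small `p` gives a large positive
#' score. Both `p` and `1 - p` are floored at `1e-300` before the ratio, so
#' the score is always finite; at `p = 1` it takes the clamp minimum.
#'
#' @param p_exact probabilities in `(0, 1]` (`NA` propagates).
#' @return Numeric vector of log-odds scores.
#' @export
#' @examples
#' log_odds(0.5)    # 0: even odds
#' log_odds(0.01)   # log10(99)
log_odds <- function(p_exact) {
  ok <- is.na(p_exact) | (p_exact > 0 & p_exact <= 1)
  if (!all(ok)) stop("`p_exact` must lie in (0, 1]")
  log10(pmax(1 - p_exact, 1e-300) / pmax(p_exact, 1e-300))
}
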