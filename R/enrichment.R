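#' Two-tailed hypergeometric probability
#'
#' Tests whether the overlap `k` between a test set of size `n` and a
#' category of size `K`, drawn without replacement from a universe of size
#' `N`, is improbably large *or* small. Uses the minimum-likelihood
#' definition of the two-sided tail: the sum of the probabilities of all
#' feasible overlaps no more probable than the observed one (a relative
#' tolerance of `1e-7` guards floating-point ties), capped at 1.
#'
#' @param N universe size.
#' @param K category size within the universe.
#' @param n test-set size.
#' @param k observed overlap; must satisfy
#'   `max(0, n + K - N) <= k <= min(n, K)`.
#'   All arguments are recycled to a common length.
#' @return Numeric vector of two-tailed probabilities in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_two_tailed(20, 5, 10, 5)
hypergeom_two_tailed <- function(N, K, n, k) {
  nn <- max(length(N), length(K), length(n), length(k))
  N <- rep_len(N, nn); K <- rep_len(K, nn)
  n <- rep_len(n, nn); k <- rep_len(k, nn)
  if (any(N < 0 | K < 0 | K > N | n < 0 | n > N))
    stop("need 0 <= K <= N and 0 <= n <= N")
  if (any(k < pmax(0, n + K - N) | k > pmin(n, K)))
    stop("overlap k outside the feasible range for (N, K, n)")
  vapply(seq_len(nn), function(i) {
    kk <- max(0, n[i] + K[i] - N[i]):min(n[i], K[i])
    pr <- dhyper(kk, K[i], N[i] - K[i], n[i])
    p0 <- pr[match(k[i], kk)]
    min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
  }, numeric(1))
}

#' Bonferroni adjustment for a stated family size
#'
#' `min(1, m * p)` for each p value, with the family size `m` given
#' explicitly (it may exceed the number of p values supplied, e.g. when only
#' a subset of a family is being reported).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param m family size; must be at least `length(p)`.
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  if (m < length(p)) stop("family size m cannot be below the number of tests")
  pmin(1, m * p)
}

#' Signed representation log odds
#'
#' The effect-size score reported next to each enrichment test: the log odds
#' that the deviation from genome-wide frequency is not chance, signed by
#' its direction. The magnitude is `log10((1 - p) / p)` of the two-tailed
#' probability (clamped as in [log_odds()]); the sign is `+1` when the
#' category is overrepresented in the test set (`k/n > K/N`), `-1` when
#' underrepresented, `0` when the frequencies coincide.
#'
#' @inheritParams hypergeom_two_tailed
#' @param p_two the two-tailed probability for `(N, K, n, k)`; computed via
#'   [hypergeom_two_tailed()] when omitted.
#' @return Signed numeric score.
#' @export
representation_log_odds <- function(N, K, n, k, p_two = NULL) {
  if (is.null(p_two)) p_two <- hypergeom_two_tailed(N, K, n, k)
  sgn <- sign(k / n - K / N)
  sgn[n == 0] <- 0
  sgn * log_odds(p_two)
}

#' Over/underrepresentation tests for gene categories
#'
#' Runs the two-tailed hypergeometric test of every category against a test
#' set within a gene universe, Bonferroni-corrects across the categories
#' tested, and reports the signed representation log odds. This one engine
#' serves both phylostratum enrichment (categories = strata) and functional
#' enrichment (categories = ontology terms).
#'
#' @param test_set character vector of genes; must be a subset of
#'   `universe`.
#' @param annotations data.frame with columns `gene`, `category`; genes
#'   outside the universe are an error. A category's size `K` is its number
#'   of distinct member genes in the universe.
#' @param universe character vector of all genes considered.
#' @param alpha familywise significance level (default 0.0025).
#' @param m Bonferroni family size; defaults to the number of categories
#'   tested in this run.
#' @param freq_log_odds also report the plain frequency log odds ratio
#'   `log10((k/(n-k)) / (K/(N-K)))` as column `freq_log_odds` (may be
#'   infinite at the boundaries).
#' @return An object of class `enrichment_result` (a data.frame), one row
#'   per category ordered by `p_two` then category id: `category`, `N`,
#'   `K`, `n`, `k`, `p_two`, `p_adj`, `rep_log_odds`, `direction`
#'   (`"over"`, `"under"` or `"none"`), `significant` (`p_adj <= alpha`).
#' @export
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g3", "g4"),
#'                   category = c("A", "A", "B", "B"))
#' enrich(c("g1", "g2"), ann, paste0("g", 1:10))
enrich <- function(test_set, annotations, universe, alpha = 0.0025,
                   m = NULL, freq_log_odds = FALSE) {
  stopifnot(is.character(test_set), is.character(universe),
            is.data.frame(annotations),
            all(c("gene", "category") %in% names(annotations)))
  universe <- unique(universe)
  test_set <- unique(test_set)
  outside <- setdiff(test_set, universe)
  if (length(outside))
    stop("test genes outside the universe: ",
         paste(head(outside, 10), collapse = ", "))
  bad_ann <- setdiff(unique(annotations$gene), universe)
  if (length(bad_ann))
    stop("annotated genes outside the universe: ",
         paste(head(bad_ann, 10), collapse = ", "))
  cats <- sort(unique(as.character(annotations$category)))
  if (is.null(m)) m <- length(cats)
  N <- length(universe); n <- length(test_set)
  rows <- lapply(cats, function(cid) {
    members <- unique(annotations$gene[annotations$category == cid])
    K <- length(members)
    k <- length(intersect(members, test_set))
    p <- hypergeom_two_tailed(N, K, n, k)
    d <- sign(k / max(n, 1) - K / N)
    out <- data.frame(
      category = cid, N = N, K = K, n = n, k = k, p_two = p,
      p_adj = bonferroni(p, m),
      rep_log_odds = representation_log_odds(N, K, n, k, p),
      direction = c("under", "none", "over")[d + 2],
      significant = bonferroni(p, m) <= alpha)
    if (freq_log_odds)
      out$freq_log_odds <- log10((k / (n - k)) / (K / (N - K)))
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p_two, res$category), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            alpha = alpha, m = m)
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat("enrichment_result:", nrow(x), "categories, Bonferroni family m =",
      attr(x, "m"), ", alpha =", attr(x, "alpha"), "\n")
  cat(" ", sum(x$significant), "significant\n")
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more categories\n")
  invisible(x)
}
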