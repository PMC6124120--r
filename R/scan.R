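#' Genome-wide bulked segregant scan
#'
#' Computes the per-SNP exact-binomial statistic over a two-pool allele-count
#' table and returns one record per SNP passing the depth filter. The score
#' is the log odds that the observed between-pool frequency difference is not
#' a chance fluctuation under resequencing at the pooled frequency (see
#' [exact_difference_probability()]).
#'
#' SNPs where either pool has fewer than `min_depth` reads are dropped (a
#' message reports how many); with `min_depth = 0`, zero-depth SNPs are kept
#' as missing values. A restriction to, e.g., non-synonymous SNPs is applied
#' upstream by subsetting the input table; the statistic itself ignores
#' allele annotation.
#'
#' @param counts a `cross_sim` from [simulate_cross()], or a data.frame in
#'   the pool-counts schema: columns `chrom`, `pos` (1-based), `refU`,
#'   `altU`, `refM`, `altM` (ref/alt counts per pool), optionally `ref`,
#'   `alt`, `alt_origin`.
#' @param min_depth minimum per-pool depth for a SNP to be scored.
#' @param sided,conditional passed to [exact_difference_probability()].
#' @return An object of class `bsa_scan` (a data.frame) with one row per
#'   scored SNP: `chrom`, `pos`, `p_hat` (pooled alt frequency), `d_obs`
#'   (observed frequency difference, multicellular minus unicellular pool),
#'   `p_exact`, `log_odds`, `neg_log10_p` and `direction` (+1 alt-allele
#'   excess in the multicellular pool, -1 in the unicellular pool, 0 none).
#' @seealso [call_regions()], [plot.bsa_scan()]
#' @export
#' @examples
#' sim <- simulate_cross(cross_config(
#'   default_genome_map(n_chrom = 2),
#'   causal_loci = data.frame(chrom = "chr01", pos = 2375000),
#'   n_f2 = 500, seed = 7))
#' sc <- bsa_scan(sim)
#' summary(sc)
bsa_scan <- function(counts, min_depth = 10, sided = c("two", "greater"),
                     conditional = FALSE) {
  sided <- match.arg(sided)
  if (inherits(counts, "cross_sim")) counts <- counts$counts
  counts <- validate_pool_counts(counts)
  if (!nrow(counts)) {
    return(empty_scan(min_depth, sided))
  }
  k_u <- counts$altU; n_u <- counts$refU + counts$altU
  k_m <- counts$altM; n_m <- counts$refM + counts$altM
  keep <- n_u >= max(min_depth, 0) & n_m >= max(min_depth, 0)
  n_drop <- sum(!keep)
  if (n_drop) {
    message(n_drop, " SNP(s) below the per-pool depth floor (min_depth = ",
            min_depth, ") skipped")
    gone <- setdiff(unique(counts$chrom), unique(counts$chrom[keep]))
    if (length(gone))
      warning("no SNPs passing the depth filter on: ",
              paste(gone, collapse = ", "))
  }
  cc <- counts[keep, , drop = FALSE]
  k_u <- k_u[keep]; n_u <- n_u[keep]; k_m <- k_m[keep]; n_m <- n_m[keep]
  zero <- n_u == 0 | n_m == 0
  if (any(zero))
    message(sum(zero), " SNP(s) with zero depth in a pool scored as missing")
  p_exact <- exact_difference_probability(k_u, n_u, k_m, n_m,
                                          sided = sided,
                                          conditional = conditional)
  d_obs <- ifelse(zero, NA_real_, k_m / n_m - k_u / n_u)
  out <- data.frame(
    chrom = cc$chrom, pos = cc$pos,
    p_hat = ifelse(zero, NA_real_, (k_u + k_m) / (n_u + n_m)),
    d_obs = d_obs,
    p_exact = p_exact,
    log_odds = log_odds(p_exact),
    neg_log10_p = -log10(p_exact),
    direction = as.integer(sign(d_obs))
  )
  rownames(out) <- NULL
  structure(out, class = c("bsa_scan", "data.frame"),
            min_depth = min_depth, sided = sided, conditional = conditional,
            n_skipped = n_drop)
}

empty_scan <- function(min_depth, sided) {
  structure(data.frame(chrom = character(), pos = integer(),
                       p_hat = numeric(), d_obs = numeric(),
                       p_exact = numeric(), log_odds = numeric(),
                       neg_log10_p = numeric(), direction = integer()),
            class = c("bsa_scan", "data.frame"),
            min_depth = min_depth, sided = sided, conditional = FALSE,
            n_skipped = 0L)
}

validate_pool_counts <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("chrom", "pos", "refU", "altU", "refM", "altM")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("pool-counts table lacks column(s): ", paste(miss, collapse = ", "))
  counts$chrom <- as.character(counts$chrom)
  if (!nrow(counts)) return(counts)
  for (v in c("refU", "altU", "refM", "altM"))
    if (any(counts[[v]] < 0)) stop("negative counts in column ", v)
  if (any(counts$pos < 1)) stop("positions must be 1-based (>= 1)")
  key <- paste(counts$chrom, counts$pos)
  if (anyDuplicated(key))
    stop("duplicated (chrom, pos): ", key[duplicated(key)][1])
  ord <- order(match(counts$chrom, unique(counts$chrom)), counts$pos)
  counts[ord, , drop = FALSE]
}

#' Merge above-threshold SNPs into candidate regions
#'
#' Groups SNPs whose log-odds score meets `threshold` into regions: SNPs on
#' the same chromosome no farther apart than `max_gap` bp join one region.
#' Regions are ranked by their peak score (ties broken by leftmost peak).
#'
#' @param scan a `bsa_scan`.
#' @param threshold minimum log-odds score (default 3, i.e. roughly
#'   `p < 1e-3`).
#' @param max_gap maximum bp gap between consecutive above-threshold SNPs in
#'   one region (> 0).
#' @return An object of class `bsa_regions` (a data.frame): `chrom`, `start`,
#'   `end` (1-based, inclusive), `peak_pos`, `peak_log_odds`, `n_snps`, in
#'   decreasing peak order. Zero rows when nothing exceeds the threshold.
#' @export
call_regions <- function(scan, threshold = 3, max_gap = 5e5) {
  stopifnot(inherits(scan, "bsa_scan"), is.finite(threshold), max_gap > 0)
  hot <- scan[!is.na(scan$log_odds) & scan$log_odds >= threshold, ,
              drop = FALSE]
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    peak_pos = integer(), peak_log_odds = numeric(),
                    n_snps = integer())
  if (nrow(hot)) {
    hot <- hot[order(match(hot$chrom, unique(scan$chrom)), hot$pos), ,
               drop = FALSE]
    new_grp <- c(TRUE, hot$chrom[-1] != hot$chrom[-nrow(hot)] |
                   diff(hot$pos) > max_gap)
    grp <- cumsum(new_grp)
    out <- do.call(rbind, lapply(split(hot, grp), function(h) {
      pk <- which(h$log_odds == max(h$log_odds))[1]  # leftmost peak on ties
      data.frame(chrom = h$chrom[1], start = min(h$pos), end = max(h$pos),
                 peak_pos = h$pos[pk], peak_log_odds = h$log_odds[pk],
                 n_snps = nrow(h))
    }))
    out <- out[order(-out$peak_log_odds, out$peak_pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("bsa_regions", "data.frame"),
            threshold = threshold, max_gap = max_gap)
}

#' @export
print.bsa_scan <- function(x, n = 6, ...) {
  cat("bsa_scan:", nrow(x), "SNPs on", length(unique(x$chrom)),
      "chromosome(s)",
      sprintf("(min_depth = %s, %s-sided)\n",
              attr(x, "min_depth"), attr(x, "sided")))
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more SNPs\n")
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, top = 5, ...) {
  cat("Bulked segregant scan over", nrow(object), "SNPs\n")
  if (!nrow(object)) return(invisible(object))
  lo <- object$log_odds[!is.na(object$log_odds)]
  cat(sprintf("  log-odds score: median %.2f, max %.2f\n",
              stats::median(lo), max(lo)))
  ord <- order(-object$log_odds)
  cat("  top SNPs:\n")
  print.data.frame(head(as.data.frame(object)[ord, c(
    "chrom", "pos", "p_hat", "d_obs", "p_exact", "log_odds")], top),
    digits = 4, row.names = FALSE)
  invisible(object)
}

#' Manhattan-style plot of a bulked segregant scan
#'
#' Plots the log-odds score against cumulative genome position, alternating
#' colour by chromosome, with an optional threshold line.
#'
#' @param x a `bsa_scan`.
#' @param threshold optional horizontal reference line (log-odds units).
#' @param col two colours to alternate between chromosomes.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.bsa_scan <- function(x, threshold = NULL,
                          col = c("grey30", "steelblue"), ...) {
  stopifnot(nrow(x) > 0)
  chroms <- unique(x$chrom)
  span <- vapply(chroms, function(cc) max(x$pos[x$chrom == cc]), numeric(1))
  offs <- setNames(c(0, cumsum(as.numeric(span)))[seq_along(chroms)], chroms)
  gx <- offs[x$chrom] + x$pos
  ci <- match(x$chrom, chroms)
  plot(gx, x$log_odds, pch = 16, cex = 0.5, col = col[1 + ci %% 2],
       xlab = "genome position", ylab = "log odds", xaxt = "n", ...)
  axis(1, at = offs + span / 2, labels = chroms, las = 2, cex.axis = 0.7)
  if (!is.null(threshold)) abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}

#' @export
print.bsa_regions <- function(x, ...) {
  cat("bsa_regions:", nrow(x), "candidate region(s) at log-odds >=",
      attr(x, "threshold"), "\n")
  if (nrow(x)) print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}
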