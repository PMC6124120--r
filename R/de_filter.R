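#' Assemble an FPKM expression matrix with sample metadata
#'
#' Wraps a gene x sample FPKM matrix together with the design of a two-strain
#' time course (ancestor vs evolved strain, several time points, replicated).
#' Sample metadata can be given explicitly or parsed from column names of the
#' form `strain_time_replicate` (e.g. `evolved_9h_r2`).
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns; FPKM values, all non-negative.
#' @param samples optional data.frame with columns `sample`, `strain`
#'   (`"ancestor"` or `"evolved"`), `time`, `replicate`, one row per column
#'   of `values`; parsed from `colnames(values)` when omitted.
#' @return An object of class `fpkm_matrix`: list with `values` and
#'   `samples`.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 1.1, 2.2, 4, 8, 4.4, 8.8), nrow = 2,
#'   dimnames = list(c("g1", "g2"),
#'     c("ancestor_3h_r1", "ancestor_3h_r2", "evolved_3h_r1",
#'       "evolved_3h_r2")))
#' fpkm_matrix(m)
fpkm_matrix <- function(values, samples = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` needs unique gene ids as rownames")
  if (any(values < 0)) stop("FPKM values must be non-negative")
  if (is.null(samples)) samples <- parse_sample_names(colnames(values))
  need <- c("sample", "strain", "time", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop("`samples` needs columns: ", paste(need, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("one metadata row per sample column is required")
  if (!all(samples$strain %in% c("ancestor", "evolved")))
    stop("strain must be 'ancestor' or 'evolved'")
  cond <- paste(samples$strain, samples$time)
  if (any(table(cond) < 2))
    stop("every (strain, time) condition needs >= 2 replicates")
  structure(list(values = values, samples = samples), class = "fpkm_matrix")
}

parse_sample_names <- function(nm) {
  if (is.null(nm)) stop("no column names to parse sample metadata from")
  parts <- strsplit(nm, "_", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("column names must look like strain_time_replicate, e.g. ",
         "evolved_9h_r2")
  data.frame(sample = nm,
             strain = vapply(parts, `[`, "", 1),
             time = vapply(parts, `[`, "", 2),
             replicate = vapply(parts, `[`, "", 3))
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat("fpkm_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  strains:", paste(unique(x$samples$strain), collapse = ", "),
      "| time points:", paste(unique(x$samples$time), collapse = ", "), "\n")
  invisible(x)
}

#' Replicate-correlation quality control
#'
#' Pearson correlation (and its square) over genes for every replicate pair
#' within each (strain, time) condition. Pairs below the floor are flagged
#' with a warning but never dropped: QC here is advisory, matching practice
#' where replicate agreement is reported rather than enforced.
#'
#' @param x an [fpkm_matrix].
#' @param floor flag threshold on `r` (default 0.98).
#' @return data.frame with one row per replicate pair: `strain`, `time`,
#'   `rep_a`, `rep_b`, `r`, `r_squared`, `flagged`. `r` is `NA` (with a
#'   warning) when a replicate vector is constant.
#' @export
replicate_correlation <- function(x, floor = 0.98) {
  stopifnot(inherits(x, "fpkm_matrix"))
  s <- x$samples
  out <- list()
  for (cond in unique(paste(s$strain, s$time))) {
    i <- which(paste(s$strain, s$time) == cond)
    for (a in seq_along(i)) for (b in seq_along(i)) {
      if (b <= a) next
      va <- x$values[, i[a]]; vb <- x$values[, i[b]]
      r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        warning("constant replicate vector in condition ", cond,
                "; correlation undefined")
        NA_real_
      } else cor(va, vb)
      out[[length(out) + 1L]] <- data.frame(
        strain = s$strain[i[a]], time = s$time[i[a]],
        rep_a = s$sample[i[a]], rep_b = s$sample[i[b]],
        r = r, r_squared = r^2,
        flagged = !is.na(r) && r < floor)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$flagged, na.rm = TRUE))
    warning(sum(res$flagged, na.rm = TRUE),
            " replicate pair(s) below the correlation floor of ", floor)
  res
}

#' Mean log2 expression ratio per gene and time point
#'
#' The fold-change statistic of the differential-expression filter:
#' `log2(mean evolved FPKM / mean ancestor FPKM)`, means taken across
#' replicates within the time point. The pseudocount rescues zeros only:
#' when either mean is zero, `c` is added to both means before the ratio, so
#' the statistic is always finite while a gene whose means sit exactly at a
#' fold boundary scores exactly `log2(fold)`.
#'
#' @param x an [fpkm_matrix].
#' @param pseudocount `c > 0`, FPKM units, used only when a mean is zero.
#' @return Numeric matrix, genes x time points, of log2 ratios
#'   (evolved over ancestor).
#' @export
mean_log2_ratio <- function(x, pseudocount = 0.1) {
  stopifnot(inherits(x, "fpkm_matrix"), pseudocount > 0)
  s <- x$samples
  times <- unique(s$time)
  out <- matrix(NA_real_, nrow(x$values), length(times),
                dimnames = list(rownames(x$values), times))
  for (tt in times) {
    me <- rowMeans(x$values[, s$strain == "evolved" & s$time == tt,
                            drop = FALSE])
    ma <- rowMeans(x$values[, s$strain == "ancestor" & s$time == tt,
                            drop = FALSE])
    zero <- me == 0 | ma == 0
    r <- log2(me / ma)
    r[zero] <- log2((me[zero] + pseudocount) / (ma[zero] + pseudocount))
    out[, tt] <- r
  }
  out
}

#' Select differentially expressed genes by fold change
#'
#' A gene is differentially expressed at a time point when the magnitude of
#' its mean log2 ratio reaches `log2(fold)` (inclusive, so an exactly
#' fourfold gene is selected under the default) and, when a significance
#' mask is supplied, the mask flags that (gene, time point). The union
#' across time points collects genes differential at one or more time
#' points; a gene may be overexpressed at one time point and underexpressed
#' at another.
#'
#' The optional mask carries an upstream statistical significance call
#' (e.g. from a count-based DE test); this package does not re-test
#' significance, it intersects the fold filter with the supplied calls.
#'
#' @param x an [fpkm_matrix].
#' @param fold fold-change threshold (> 1); default 4, i.e. `log2 >= 2`.
#' @param pseudocount passed to [mean_log2_ratio()].
#' @param mask optional logical matrix (genes x time points, dimnames
#'   matching) of significance flags.
#' @return An object of class `de_gene_sets`: list with
#'   `per_time` (named list of data.frames `gene`, `log2_ratio`, `sign`),
#'   `union` (character vector of genes differential at >= 1 time point),
#'   `log2_ratio` (the full ratio matrix), `fold`.
#' @export
select_de_genes <- function(x, fold = 4, pseudocount = 0.1, mask = NULL) {
  stopifnot(inherits(x, "fpkm_matrix"), fold > 1)
  lr <- mean_log2_ratio(x, pseudocount)
  thr <- log2(fold)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask))
    if (!all(rownames(lr) %in% rownames(mask)) ||
        !all(colnames(lr) %in% colnames(mask)))
      stop("`mask` must cover every gene and time point")
    mask <- mask[rownames(lr), colnames(lr), drop = FALSE]
  }
  per_time <- lapply(colnames(lr), function(tt) {
    sel <- abs(lr[, tt]) >= thr
    if (!is.null(mask)) sel <- sel & mask[, tt]
    g <- rownames(lr)[sel]
    data.frame(gene = g, log2_ratio = lr[sel, tt],
               sign = as.integer(sign(lr[sel, tt])), row.names = NULL)
  })
  names(per_time) <- colnames(lr)
  structure(list(
    per_time = per_time,
    union = sort(unique(unlist(lapply(per_time, `[[`, "gene")))),
    log2_ratio = lr, fold = fold
  ), class = "de_gene_sets")
}

#' @export
print.de_gene_sets <- function(x, ...) {
  cat("de_gene_sets: fold threshold", x$fold,
      sprintf("(|log2 ratio| >= %.3g)\n", log2(x$fold)))
  for (tt in names(x$per_time)) {
    d <- x$per_time[[tt]]
    cat(sprintf("  %s: %d genes (%d over, %d under)\n", tt, nrow(d),
                sum(d$sign > 0), sum(d$sign < 0)))
  }
  cat("  union:", length(x$union), "genes at >= 1 time point\n")
  invisible(x)
}
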