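#' Ordered ladder of nested taxonomic strata
#'
#' A stratum ladder orders nested taxonomic groups from least to most
#' inclusive, together with a mapping from homology-hit subject taxa to the
#' least-inclusive stratum containing them. The default ladder is the
#' eight-step series used for the volvocine green algae: *Chlamydomonas*,
#' volvocine (*Chlamydomonas* + *Gonium* + *Volvox* clade),
#' Chlamydomonadales, Chlorophyceae, Chlorophyta, Viridiplantae, Eukaryota,
#' cellular organisms.
#'
#' @param strata character vector of stratum names, least inclusive first.
#' @param taxon_map data.frame with columns `taxon`, `stratum` mapping
#'   subject taxon identifiers to strata; every `stratum` value must be on
#'   the ladder, each taxon mapped once.
#' @return An object of class `stratum_ladder`.
#' @export
#' @examples
#' tm <- data.frame(taxon = c("Chlamydomonas_reinhardtii", "Volvox_carteri",
#'                            "Arabidopsis_thaliana", "Escherichia_coli"),
#'                  stratum = c("Chlamydomonas", "volvocine",
#'                              "Viridiplantae", "cellular organisms"))
#' stratum_ladder(taxon_map = tm)
stratum_ladder <- function(strata = default_strata(), taxon_map) {
  stopifnot(is.character(strata), length(strata) >= 1,
            !anyDuplicated(strata))
  stopifnot(is.data.frame(taxon_map),
            all(c("taxon", "stratum") %in% names(taxon_map)))
  taxon_map$taxon <- as.character(taxon_map$taxon)
  taxon_map$stratum <- as.character(taxon_map$stratum)
  if (anyDuplicated(taxon_map$taxon))
    stop("each taxon must map to exactly one stratum")
  bad <- setdiff(taxon_map$stratum, strata)
  if (length(bad))
    stop("taxon_map references strata not on the ladder: ",
         paste(bad, collapse = ", "))
  structure(list(strata = strata, taxon_map = taxon_map),
            class = "stratum_ladder")
}

#' @rdname stratum_ladder
#' @export
default_strata <- function() {
  c("Chlamydomonas", "volvocine", "Chlamydomonadales", "Chlorophyceae",
    "Chlorophyta", "Viridiplantae", "Eukaryota", "cellular organisms")
}

#' @export
print.stratum_ladder <- function(x, ...) {
  cat("stratum_ladder (least -> most inclusive):\n  ",
      paste(x$strata, collapse = " < "), "\n")
  cat("  taxon map:", nrow(x$taxon_map), "taxa\n")
  invisible(x)
}

#' Filter homology hits by E-value
#'
#' Retains hits considered homologous: E-value strictly below `e_max`. The
#' cut is strict, so a hit at exactly the threshold is discarded. Input
#' order is preserved.
#'
#' @param hits data.frame with columns `qseqid` (query gene), `sseqid`
#'   (subject), `evalue` and `staxid` (subject taxon), i.e. the tabular
#'   output of a protein homology search.
#' @param e_max threshold, default `0.001`.
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, e_max = 0.001) {
  stopifnot(is.data.frame(hits), e_max > 0)
  need <- c("qseqid", "evalue")
  if (!all(need %in% names(hits)))
    stop("`hits` needs at least columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(hits$evalue)) || any(hits$evalue < 0))
    stop("E-values must be finite and non-negative")
  hits[hits$evalue < e_max, , drop = FALSE]
}

#' Assign genes to phylostrata
#'
#' Each gene's phylostratum is the *most* inclusive stratum among its
#' filtered hits' taxa — the oldest taxonomic level at which homology is
#' detectable, a proxy for the gene's evolutionary age. A gene with no
#' surviving non-self hit is assigned the least-inclusive stratum
#' (lineage-specific). A hit whose subject id equals the query id is treated
#' as the query's own database record and excluded before assignment.
#'
#' @param genes character vector: the query universe; every gene gets an
#'   assignment.
#' @param hits data.frame of homology hits (columns `qseqid`, `sseqid`,
#'   `evalue`, `staxid`); pass the raw table — filtering with `e_max` happens
#'   here.
#' @param ladder a [stratum_ladder].
#' @param e_max E-value threshold for [filter_hits()].
#' @param unresolved how to treat hit taxa absent from the ladder's taxon
#'   map: `"skip"` drops them with a warning, `"error"` aborts.
#' @return data.frame `gene`, `stratum`, `stratum_rank` (1 = least
#'   inclusive), one row per input gene.
#' @export
#' @examples
#' tm <- data.frame(taxon = c("Vc", "At"),
#'                  stratum = c("volvocine", "Viridiplantae"))
#' hits <- data.frame(qseqid = "g1", sseqid = c("Vc_p1", "At_p9"),
#'                    evalue = c(1e-50, 1e-6), staxid = c("Vc", "At"))
#' assign_phylostrata(c("g1", "g2"), hits, stratum_ladder(taxon_map = tm))
assign_phylostrata <- function(genes, hits, ladder, e_max = 0.001,
                               unresolved = c("skip", "error")) {
  unresolved <- match.arg(unresolved)
  stopifnot(is.character(genes), length(genes) >= 1, !anyDuplicated(genes),
            inherits(ladder, "stratum_ladder"))
  hits <- filter_hits(hits, e_max)
  if (!all(c("sseqid", "staxid") %in% names(hits)))
    stop("`hits` needs columns sseqid and staxid for assignment")
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]  # self records
  unknown_gene <- setdiff(unique(hits$qseqid), genes)
  if (length(unknown_gene))
    stop("hits reference genes outside the query universe: ",
         paste(head(unknown_gene, 5), collapse = ", "))
  rank <- match(hits$staxid, ladder$taxon_map$taxon)
  if (anyNA(rank)) {
    bad <- unique(hits$staxid[is.na(rank)])
    if (unresolved == "error")
      stop("unresolvable hit taxa: ", paste(head(bad, 5), collapse = ", "))
    warning(length(bad), " hit taxon/taxa not in the taxon map skipped: ",
            paste(head(bad, 5), collapse = ", "))
    hits <- hits[!is.na(rank), , drop = FALSE]
    rank <- rank[!is.na(rank)]
  }
  srank <- match(ladder$taxon_map$stratum[rank], ladder$strata)
  best <- tapply(srank, hits$qseqid, max)
  out_rank <- rep(1L, length(genes))
  hit_idx <- match(genes, names(best))
  out_rank[!is.na(hit_idx)] <- as.integer(best[hit_idx[!is.na(hit_idx)]])
  data.frame(gene = genes, stratum = ladder$strata[out_rank],
             stratum_rank = out_rank)
}

#' Genome-wide stratum census
#'
#' Counts genes per stratum across a gene universe; these counts are the
#' expected (background) frequencies of the enrichment tests.
#'
#' @param assignments data.frame from [assign_phylostrata()].
#' @param universe character vector of gene ids; every universe gene must be
#'   assigned.
#' @param ladder the [stratum_ladder] used for assignment (fixes the row
#'   order and includes zero-count strata).
#' @return data.frame `stratum`, `count`; counts sum to `length(universe)`.
#' @export
stratum_census <- function(assignments, universe, ladder) {
  stopifnot(inherits(ladder, "stratum_ladder"), !anyDuplicated(universe))
  i <- match(universe, assignments$gene)
  if (anyNA(i))
    stop("assignments do not cover the universe: ",
         paste(head(universe[is.na(i)], 5), collapse = ", "))
  counts <- table(factor(assignments$stratum[i], levels = ladder$strata))
  data.frame(stratum = ladder$strata, count = as.integer(counts))
}
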