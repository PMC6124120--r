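#' Define a marker map for a haploid genome
#'
#' A `genome_map` holds the chromosome table (physical length in bp, genetic
#' length in Morgans) and the ordered biallelic marker positions segregating
#' between the two parents of a cross. It is the coordinate system used by the
#' cross simulator: crossovers are placed on the genetic map and markers are
#' located by interpolating physical position linearly onto it.
#'
#' @param chromosomes data.frame with columns `chrom` (id), `length_bp`
#'   (physical length, bp) and `length_morgan` (genetic length, Morgans).
#' @param markers data.frame with columns `chrom` and `pos` (1-based bp);
#'   positions must be strictly increasing within a chromosome and lie in
#'   `[1, length_bp]`.
#' @return An object of class `genome_map`: a list with elements `chromosomes`
#'   and `markers` (the latter gains a `gpos` column, the marker's genetic
#'   position in Morgans).
#' @seealso [default_genome_map()] for a ready-made synthetic genome.
#' @export
#' @examples
#' gm <- genome_map(
#'   data.frame(chrom = "chr1", length_bp = 1e6, length_morgan = 1),
#'   data.frame(chrom = "chr1", pos = c(1e5, 5e5, 9e5))
#' )
#' gm
genome_map <- function(chromosomes, markers) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(markers))
  need_c <- c("chrom", "length_bp", "length_morgan")
  if (!all(need_c %in% names(chromosomes)))
    stop("`chromosomes` needs columns: ", paste(need_c, collapse = ", "))
  if (!all(c("chrom", "pos") %in% names(markers)))
    stop("`markers` needs columns: chrom, pos")
  if (nrow(chromosomes) < 1L) stop("at least one chromosome is required")
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome ids")
  if (any(chromosomes$length_bp < 1) || any(chromosomes$length_morgan < 0))
    stop("chromosome lengths must be positive (bp) and non-negative (Morgans)")
  if (!all(markers$chrom %in% chromosomes$chrom))
    stop("markers reference unknown chromosomes")

  chromosomes$chrom <- as.character(chromosomes$chrom)
  markers$chrom <- as.character(markers$chrom)
  ord <- order(match(markers$chrom, chromosomes$chrom), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  for (cc in chromosomes$chrom) {
    p <- markers$pos[markers$chrom == cc]
    len <- chromosomes$length_bp[chromosomes$chrom == cc]
    if (length(p) && (any(p < 1) || any(p > len)))
      stop("marker positions outside [1, length_bp] on ", cc)
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("marker positions must be strictly increasing on ", cc)
  }
  i <- match(markers$chrom, chromosomes$chrom)
  markers$gpos <- markers$pos / chromosomes$length_bp[i] *
    chromosomes$length_morgan[i]
  rownames(markers) <- NULL
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_map")
}

#' Synthetic genome map with evenly spaced markers
#'
#' Convenience constructor for simulation studies: `n_chrom` chromosomes of
#' equal physical and genetic length carrying `markers_per_chrom` evenly
#' spaced markers each. The defaults (17 chromosomes, 20 markers each, 1
#' Morgan, 5 Mb) mirror the karyotype of *Chlamydomonas reinhardtii* at a
#' marker density convenient for pooled-cross simulations.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param length_bp physical chromosome length (bp).
#' @param length_morgan genetic chromosome length (Morgans).
#' @return A [genome_map].
#' @export
default_genome_map <- function(n_chrom = 17, markers_per_chrom = 20,
                               length_bp = 5e6, length_morgan = 1) {
  chroms <- data.frame(
    chrom = sprintf("chr%02d", seq_len(n_chrom)),
    length_bp = length_bp, length_morgan = length_morgan
  )
  pos <- round(length_bp * (seq_len(markers_per_chrom) - 0.5) /
                 markers_per_chrom)
  markers <- data.frame(
    chrom = rep(chroms$chrom, each = markers_per_chrom),
    pos = rep(pos, n_chrom)
  )
  genome_map(chroms, markers)
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$markers), "marker(s)\n")
  cat("  total genetic length:",
      sum(x$chromosomes$length_morgan), "Morgans\n")
  invisible(x)
}

n_markers <- function(map) nrow(map$markers)

marker_index <- function(map, chrom, pos) {
  i <- match(paste(chrom, pos), paste(map$markers$chrom, map$markers$pos))
  if (anyNA(i)) {
    bad <- paste0(chrom[is.na(i)], ":", pos[is.na(i)], collapse = ", ")
    stop("locus not on a marker of the genome map: ", bad)
  }
  i
}
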