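#' Configure a synthetic haploid F2 cross
#'
#' Bundles everything [simulate_cross()] needs: the marker map, the causal
#' loci and the genotype-to-phenotype rule, the imperfection of the
#' phenotype-based pool separation, and the pooled-sequencing model.
#'
#' The phenotype rule acts on the alleles an F2 individual carries at the
#' causal loci, where "derived" means the multicellular parent's allele:
#' `"ALL"` calls an individual multicellular iff it carries the derived allele
#' at every causal locus; `"ANY"` iff at any one. Pool separation is modelled
#' as a single stochastic sorting step: each individual lands in the pool
#' matching its phenotype with probability `1 - misclass_rate`.
#'
#' @param genome a [genome_map].
#' @param causal_loci data.frame with columns `chrom`, `pos`; every causal
#'   locus must coincide with a marker. May have zero rows (no causal locus).
#' @param phenotype_model `"ALL"` or `"ANY"`.
#' @param misclass_rate probability an individual is sorted into the wrong
#'   pool, in `[0, 1)`.
#' @param depth_unicellular,depth_multicellular mean sequencing depth per SNP
#'   (reads) for the unicellular- and multicellular-enriched pool.
#' @param seq_error_rate per-read probability the observed allele is flipped,
#'   in `[0, 0.05]`.
#' @param n_f2 number of F2 individuals (>= 2).
#' @param n_f1 size of the intermediate F1 pool from which F2 parents are
#'   drawn.
#' @param seed integer random seed; fixed seed gives byte-identical output.
#' @param depth_dispersion optional negative-binomial size parameter for the
#'   per-SNP depth distribution; `NULL` (default) uses Poisson depths.
#' @param growth_locus optional single-row data.frame (`chrom`, `pos`) naming
#'   a marker whose derived allele multiplies an individual's chance of being
#'   sampled by a read, emulating a growth-rate advantage during the outgrowth
#'   of the pools; `NULL` disables it.
#' @param growth_advantage fitness multiplier at `growth_locus` (>= 0).
#' @return An object of class `cross_config` (a validated list).
#' @export
#' @examples
#' cfg <- cross_config(
#'   genome = default_genome_map(),
#'   causal_loci = data.frame(chrom = c("chr14", "chr16"),
#'                            pos = c(2375000, 2375000)),
#'   seed = 1
#' )
#' cfg
cross_config <- function(genome,
                         causal_loci = data.frame(chrom = character(),
                                                  pos = integer()),
                         phenotype_model = c("ALL", "ANY"),
                         misclass_rate = 0.05,
                         depth_unicellular = 155,
                         depth_multicellular = 128,
                         seq_error_rate = 0.002,
                         n_f2 = 2000,
                         n_f1 = 200,
                         seed = 1L,
                         depth_dispersion = NULL,
                         growth_locus = NULL,
                         growth_advantage = 1) {
  if (!inherits(genome, "genome_map")) stop("`genome` must be a genome_map")
  phenotype_model <- match.arg(phenotype_model)
  stopifnot(is.data.frame(causal_loci))
  if (nrow(causal_loci))
    marker_index(genome, causal_loci$chrom, causal_loci$pos)  # must be markers
  if (!is.null(growth_locus)) {
    stopifnot(is.data.frame(growth_locus), nrow(growth_locus) == 1L)
    marker_index(genome, growth_locus$chrom, growth_locus$pos)
    stopifnot(growth_advantage >= 0)
  }
  if (misclass_rate < 0 || misclass_rate >= 1)
    stop("`misclass_rate` must be in [0, 1)")
  if (depth_unicellular <= 0 || depth_multicellular <= 0)
    stop("mean pool depths must be > 0")
  if (seq_error_rate < 0 || seq_error_rate > 0.05)
    stop("`seq_error_rate` must be in [0, 0.05]")
  if (n_f2 < 2) stop("`n_f2` must be >= 2")
  if (n_f1 < 2) stop("`n_f1` must be >= 2")
  if (!is.null(depth_dispersion) && depth_dispersion <= 0)
    stop("`depth_dispersion` must be > 0 (or NULL for Poisson depths)")
  structure(list(
    genome = genome, causal_loci = causal_loci,
    phenotype_model = phenotype_model, misclass_rate = misclass_rate,
    depth_unicellular = depth_unicellular,
    depth_multicellular = depth_multicellular,
    seq_error_rate = seq_error_rate, n_f2 = as.integer(n_f2),
    n_f1 = as.integer(n_f1), seed = as.integer(seed),
    depth_dispersion = depth_dispersion, growth_locus = growth_locus,
    growth_advantage = growth_advantage
  ), class = "cross_config")
}

#' @export
print.cross_config <- function(x, ...) {
  cat("cross_config:\n")
  cat("  genome: ", nrow(x$genome$chromosomes), " chromosomes, ",
      n_markers(x$genome), " markers\n", sep = "")
  if (nrow(x$causal_loci)) {
    cat("  causal loci (", x$phenotype_model, " model): ",
        paste0(x$causal_loci$chrom, ":", x$causal_loci$pos, collapse = ", "),
        "\n", sep = "")
  } else cat("  causal loci: none (null cross)\n")
  cat("  n_f2 =", x$n_f2, " n_f1 =", x$n_f1,
      " misclass_rate =", x$misclass_rate, "\n")
  cat("  depths (U/M) =", x$depth_unicellular, "/", x$depth_multicellular,
      " seq_error_rate =", x$seq_error_rate, " seed =", x$seed, "\n")
  invisible(x)
}
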