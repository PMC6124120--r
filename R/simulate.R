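#' Simulate one meiosis between two haploid parents
#'
#' Produces a recombinant haploid genome. Per chromosome, the number of
#' crossovers is Poisson with mean equal to the chromosome's genetic length in
#' Morgans (no interference, i.e. Haldane's model), crossover positions are
#' uniform on the genetic map, and the starting parent of the chromatid is
#' chosen with probability 1/2. Each marker inherits the active parent's
#' allele between crossovers.
#'
#' Uses the session RNG; call `set.seed()` (or use [simulate_cross()], which
#' seeds itself) for reproducibility.
#'
#' @param parent_a,parent_b haploid genotypes: numeric vectors with one allele
#'   (0/1) per marker of `map`, in marker order.
#' @param map a [genome_map].
#' @return A recombinant genotype vector of the same length.
#' @export
simulate_meiosis <- function(parent_a, parent_b, map) {
  m <- n_markers(map)
  if (length(parent_a) != m || length(parent_b) != m)
    stop("parents must be defined at every marker of the genome map")
  drop(meiosis_population(matrix(parent_a, 1), matrix(parent_b, 1), map))
}

# Vectorised meiosis: row i of A and B are the two parents of offspring i.
meiosis_population <- function(A, B, map) {
  n <- nrow(A)
  mk <- map$markers
  out <- matrix(0L, n, nrow(mk))
  for (ci in seq_len(nrow(map$chromosomes))) {
    cc <- map$chromosomes$chrom[ci]
    L <- map$chromosomes$length_morgan[ci]
    idx <- which(mk$chrom == cc)
    if (!length(idx)) next
    g <- mk$gpos[idx]
    k <- rpois(n, L)
    start_a <- runif(n) < 0.5
    parity <- matrix(0L, n, length(idx))
    for (i in which(k > 0L)) {
      xo <- sort.int(runif(k[i], 0, L))
      parity[i, ] <- findInterval(g, xo) %% 2L
    }
    # element [i, j] compares parity with start_a[i] (column-major recycling)
    use_a <- (parity == 0L) == start_a
    seg <- A[, idx, drop = FALSE]
    seg[!use_a] <- B[, idx, drop = FALSE][!use_a]
    out[, idx] <- seg
  }
  storage.mode(out) <- "integer"
  out
}

#' Simulate a haploid F2 population
#'
#' Crosses the two fully homozygous parental genotypes (all-derived
#' multicellular parent vs all-ancestral unicellular parent) to produce an F1
#' pool of `n_f1` recombinants, then draws each F2 individual as the meiotic
#' product of a random pair of distinct F1 parents.
#'
#' @param config a [cross_config].
#' @param reset_seed set the RNG to `config$seed` first (default `TRUE`);
#'   [simulate_cross()] calls with `FALSE` because it manages the seed itself.
#' @return Integer matrix `n_f2` x markers; 1 = multicellular-parent (derived)
#'   allele, 0 = unicellular-parent allele. Marker order follows the map.
#' @export
simulate_f2_population <- function(config, reset_seed = TRUE) {
  stopifnot(inherits(config, "cross_config"))
  if (reset_seed) set.seed(config$seed)
  map <- config$genome
  m <- n_markers(map)
  p_multi <- matrix(1L, config$n_f1, m)
  p_uni <- matrix(0L, config$n_f1, m)
  f1 <- meiosis_population(p_multi, p_uni, map)
  pa <- sample.int(config$n_f1, config$n_f2, replace = TRUE)
  pb <- (pa + sample.int(config$n_f1 - 1L, config$n_f2, replace = TRUE) - 1L) %%
    config$n_f1 + 1L
  meiosis_population(f1[pa, , drop = FALSE], f1[pb, , drop = FALSE], map)
}

#' Phenotype of F2 individuals from their causal-locus alleles
#'
#' Deterministic application of the configured rule: under `"ALL"` an
#' individual is multicellular iff it carries the derived allele at every
#' causal locus, under `"ANY"` iff at any causal locus. With zero causal loci
#' the rules degenerate (`"ALL"` is vacuously multicellular, `"ANY"`
#' unicellular); [simulate_cross()] instead sorts a null cross at random.
#'
#' @param genotypes genotype vector or matrix (individuals x markers).
#' @param config a [cross_config] whose causal loci lie on markers of its map.
#' @return Character vector, `"unicellular"` or `"multicellular"`.
#' @export
assign_phenotype <- function(genotypes, config) {
  stopifnot(inherits(config, "cross_config"))
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, 1)
  idx <- if (nrow(config$causal_loci))
    marker_index(config$genome, config$causal_loci$chrom,
                 config$causal_loci$pos) else integer()
  cg <- genotypes[, idx, drop = FALSE]
  multi <- if (config$phenotype_model == "ALL")
    rowSums(cg == 1L) == length(idx)
  else
    rowSums(cg == 1L) > 0L
  ifelse(multi, "multicellular", "unicellular")
}

#' Sort individuals into phenotype-enriched pools
#'
#' Models the repeated growth-and-centrifugation enrichment as a single
#' stochastic sorting step: each individual joins the pool matching its
#' phenotype with probability `1 - misclass_rate` and the other pool
#' otherwise. Uses the session RNG.
#'
#' @param phenotypes character vector from [assign_phenotype()].
#' @param misclass_rate probability of sorting an individual into the wrong
#'   pool, in `[0, 1)`.
#' @return List with integer index vectors `U` (unicellular-enriched pool)
#'   and `M` (multicellular-enriched pool); either may be empty.
#' @export
select_pools <- function(phenotypes, misclass_rate) {
  if (misclass_rate < 0 || misclass_rate >= 1)
    stop("`misclass_rate` must be in [0, 1)")
  is_multi <- phenotypes == "multicellular"
  flip <- runif(length(phenotypes)) < misclass_rate
  in_m <- xor(is_multi, flip)
  list(U = which(!in_m), M = which(in_m))
}

#' Sample pooled sequencing read counts for one pool
#'
#' Per SNP the read depth is Poisson with the pool's mean depth (or negative
#' binomial when a dispersion size is given); each read comes from a uniformly
#' random pool member (optionally fitness-weighted) and reports that member's
#' allele, flipped with the per-read error probability. Uses the session RNG.
#'
#' @param genotypes integer matrix (pool members x markers).
#' @param map the [genome_map] the genotypes are defined on.
#' @param mean_depth mean reads per SNP (> 0).
#' @param seq_error_rate per-read allele flip probability.
#' @param depth_dispersion optional negative-binomial size; `NULL` = Poisson.
#' @param weights optional per-member sampling weights (e.g. growth-rate
#'   fitness); default uniform.
#' @return data.frame with columns `chrom`, `pos`, `ref_count`, `alt_count`
#'   (alt = derived, multicellular-parent allele).
#' @export
sample_pool_reads <- function(genotypes, map, mean_depth, seq_error_rate = 0,
                              depth_dispersion = NULL, weights = NULL) {
  if (is.null(dim(genotypes)) || nrow(genotypes) == 0L)
    stop("cannot sequence an empty pool")
  if (mean_depth <= 0) stop("`mean_depth` must be > 0")
  m <- n_markers(map)
  stopifnot(ncol(genotypes) == m)
  f <- if (is.null(weights)) colMeans(genotypes == 1L) else {
    stopifnot(length(weights) == nrow(genotypes), all(weights >= 0),
              sum(weights) > 0)
    colSums((genotypes == 1L) * weights) / sum(weights)
  }
  depth <- if (is.null(depth_dispersion)) rpois(m, mean_depth)
  else rnbinom(m, size = depth_dispersion, mu = mean_depth)
  p_obs <- f * (1 - seq_error_rate) + (1 - f) * seq_error_rate
  alt <- rbinom(m, depth, p_obs)
  data.frame(chrom = map$markers$chrom, pos = map$markers$pos,
             ref_count = depth - alt, alt_count = alt)
}

#' Simulate a full bulked-segregant experiment with known truth
#'
#' Runs the whole generative model: F2 population, phenotypes, imperfect pool
#' sorting, and depth-sampled pooled read counts for both pools. The RNG is
#' seeded from `config$seed`, so an identical config yields byte-identical
#' output. When the config has no causal locus the population is sorted into
#' two pools at random (a null cross), since no genotype then determines
#' settling behaviour.
#'
#' @param config a [cross_config].
#' @return An object of class `cross_sim`: list with
#'   \describe{
#'     \item{counts}{data.frame in the pool-counts schema (`chrom`, `pos`,
#'       `ref`, `alt`, `refU`, `altU`, `refM`, `altM`, `alt_origin`); the alt
#'       allele is always the multicellular parent's.}
#'     \item{truth}{ground-truth ledger: causal loci, phenotype model and all
#'       generator parameters, for parameter-recovery studies.}
#'     \item{genotypes}{the F2 genotype matrix.}
#'     \item{phenotypes}{per-individual phenotype.}
#'     \item{pools}{index vectors `U` and `M`.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cross(cross_config(default_genome_map(n_chrom = 2),
#'                                    n_f2 = 200, seed = 42))
#' head(sim$counts)
simulate_cross <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  set.seed(config$seed)
  geno <- simulate_f2_population(config, reset_seed = FALSE)
  phen <- if (nrow(config$causal_loci)) assign_phenotype(geno, config)
  else ifelse(runif(config$n_f2) < 0.5, "multicellular", "unicellular")
  pools <- select_pools(phen, config$misclass_rate)
  if (!length(pools$U) || !length(pools$M))
    stop("a pool is empty; increase n_f2 or revisit the phenotype model")
  w <- NULL
  if (!is.null(config$growth_locus)) {
    gi <- marker_index(config$genome, config$growth_locus$chrom,
                       config$growth_locus$pos)
    w_all <- config$growth_advantage^(geno[, gi] == 1L)
  }
  wU <- if (!is.null(config$growth_locus)) w_all[pools$U] else NULL
  wM <- if (!is.null(config$growth_locus)) w_all[pools$M] else NULL
  u <- sample_pool_reads(geno[pools$U, , drop = FALSE], config$genome,
                         config$depth_unicellular, config$seq_error_rate,
                         config$depth_dispersion, wU)
  m <- sample_pool_reads(geno[pools$M, , drop = FALSE], config$genome,
                         config$depth_multicellular, config$seq_error_rate,
                         config$depth_dispersion, wM)
  counts <- data.frame(
    chrom = u$chrom, pos = u$pos, ref = "A", alt = "C",
    refU = u$ref_count, altU = u$alt_count,
    refM = m$ref_count, altM = m$alt_count,
    alt_origin = TRUE
  )
  structure(list(
    counts = counts,
    truth = list(causal_loci = config$causal_loci,
                 phenotype_model = config$phenotype_model,
                 config = config),
    genotypes = geno, phenotypes = phen, pools = pools
  ), class = "cross_sim")
}

#' @export
print.cross_sim <- function(x, ...) {
  cat("cross_sim:", nrow(x$genotypes), "F2 individuals,",
      nrow(x$counts), "SNPs\n")
  cat("  pools: U =", length(x$pools$U), " M =", length(x$pools$M), "\n")
  if (nrow(x$truth$causal_loci)) {
    cat("  causal loci:",
        paste0(x$truth$causal_loci$chrom, ":", x$truth$causal_loci$pos,
               collapse = ", "), "\n")
  } else cat("  null cross (no causal locus)\n")
  invisible(x)
}
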