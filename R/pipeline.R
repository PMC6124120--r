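#' Replication-mode default parameters
#'
#' The parameter set that reproduces the original study's analysis choices
#' in one place: fourfold expression filter (`log2 >= 2`), strict homology
#' E-value cut at 0.001, familywise `alpha = 0.0025` for the two-tailed
#' hypergeometric tests, two-sided exact binomial scan. The remaining
#' entries are this package's own defaults for knobs the study leaves open
#' (pseudocount, per-pool depth floor, region-calling threshold and gap,
#' replicate-correlation floor).
#'
#' @return Named list of defaults consumed by the pipeline stages.
#' @export
#' @examples
#' replication_defaults()
replication_defaults <- function() {
  list(
    fold = 4,            # DE filter: fourfold, i.e. |log2 ratio| >= 2
    e_max = 0.001,       # homology E-value cut, strict
    alpha = 0.0025,      # familywise level of the enrichment tests
    sided = "two",       # two-sided exact binomial scan
    pseudocount = 0.1,   # FPKM zero-rescue
    cor_floor = 0.98,    # replicate-correlation QC flag
    min_depth = 10,      # per-pool depth floor in the scan
    threshold = 3,       # region-calling log-odds cutoff
    max_gap = 5e5        # region-merging gap (bp)
  )
}

known_config_keys <- list(
  top = c("seed", "outdir", "stages", "simulate", "scan", "regions",
          "de", "strata", "enrich"),
  simulate = c("n_chrom", "markers_per_chrom", "length_bp", "length_morgan",
               "causal_loci", "phenotype_model", "misclass_rate",
               "depth_unicellular", "depth_multicellular", "seq_error_rate",
               "n_f2", "n_f1", "depth_dispersion"),
  scan = c("counts", "min_depth", "sided", "conditional"),
  regions = c("scan", "threshold", "max_gap"),
  de = c("fpkm", "fold", "pseudocount"),
  strata = c("hits", "taxa", "universe", "e_max", "strata_order"),
  enrich = c("set", "annot", "universe", "alpha", "m")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Run the pipeline stages from a single configuration
#'
#' Executes the requested stages in dependency order
#' (`simulate -> scan -> regions`; `de`; `strata`; `enrich`), writing each
#' stage's artifact into the output directory plus a `manifest.json`
#' recording the package version, seed, resolved parameters and the MD5
#' checksum of every output. A fixed seed gives byte-identical outputs on
#' repeated runs. Unknown configuration keys are rejected; stage parameters
#' default to [replication_defaults()].
#'
#' Stage inputs: `scan` uses the `simulate` stage's counts or an explicit
#' `scan$counts` path; `regions` uses the `scan` stage's output or an
#' explicit `regions$scan` path; `enrich` uses the `de` stage's union gene
#' set or an explicit `enrich$set` path. A missing upstream is an error
#' naming the absent stage.
#'
#' @param config a named list, or the path of a YAML file holding one. Top
#'   level: `seed`, `outdir`, `stages` (character vector) and one block per
#'   stage.
#' @param outdir output directory (overrides `config$outdir`).
#' @return Invisibly, a named list of artifact paths.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(list(
#'   seed = 1, stages = c("simulate", "scan", "regions"),
#'   simulate = list(n_chrom = 2, n_f2 = 300,
#'     causal_loci = list(list(chrom = "chr01", pos = 2375000)))),
#'   outdir = tempfile("segscan"))
#' }
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  check_keys(config, known_config_keys$top, "top level")
  defaults <- replication_defaults()
  seed <- as.integer(config$seed %||% 1L)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "scan", "regions")
  order_all <- c("simulate", "scan", "regions", "de", "strata", "enrich")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- order_all[order_all %in% stages]
  art <- list()
  params <- list(seed = seed, stages = stages)

  sim <- NULL
  scan <- NULL
  de <- NULL

  if ("simulate" %in% stages) {
    sc <- config$simulate %||% list()
    check_keys(sc, known_config_keys$simulate, "simulate")
    gm <- default_genome_map(
      n_chrom = sc$n_chrom %||% 17,
      markers_per_chrom = sc$markers_per_chrom %||% 20,
      length_bp = sc$length_bp %||% 5e6,
      length_morgan = sc$length_morgan %||% 1)
    cl <- if (is.null(sc$causal_loci))
      data.frame(chrom = character(), pos = integer())
    else do.call(rbind, lapply(sc$causal_loci, function(l)
      data.frame(chrom = l$chrom, pos = l$pos)))
    cfg <- cross_config(
      genome = gm, causal_loci = cl,
      phenotype_model = sc$phenotype_model %||% "ALL",
      misclass_rate = sc$misclass_rate %||% 0.05,
      depth_unicellular = sc$depth_unicellular %||% 155,
      depth_multicellular = sc$depth_multicellular %||% 128,
      seq_error_rate = sc$seq_error_rate %||% 0.002,
      n_f2 = sc$n_f2 %||% 2000, n_f1 = sc$n_f1 %||% 200,
      seed = seed, depth_dispersion = sc$depth_dispersion)
    sim <- simulate_cross(cfg)
    art$counts <- file.path(outdir, "counts.tsv")
    write_pool_counts(sim, art$counts)
    art$truth <- file.path(outdir, "truth.tsv")
    write_tsv(if (nrow(cl)) cl else
      data.frame(chrom = character(), pos = integer()), art$truth)
    params$simulate <- cfg[setdiff(names(cfg), "genome")]
  }

  if ("scan" %in% stages) {
    sc <- config$scan %||% list()
    check_keys(sc, known_config_keys$scan, "scan")
    counts <- if (!is.null(sim)) sim$counts
    else if (!is.null(sc$counts)) read_pool_counts(sc$counts)
    else stop("scan stage needs the simulate stage or scan$counts")
    scan <- bsa_scan(counts,
                     min_depth = sc$min_depth %||% defaults$min_depth,
                     sided = sc$sided %||% defaults$sided,
                     conditional = isTRUE(sc$conditional))
    art$scan <- file.path(outdir, "scan.tsv")
    write_scan(scan, art$scan)
    params$scan <- list(min_depth = sc$min_depth %||% defaults$min_depth,
                        sided = sc$sided %||% defaults$sided)
  }

  if ("regions" %in% stages) {
    rc <- config$regions %||% list()
    check_keys(rc, known_config_keys$regions, "regions")
    sc_in <- if (!is.null(scan)) scan
    else if (!is.null(rc$scan)) read_scan(rc$scan)
    else stop("regions stage needs the scan stage or regions$scan")
    regs <- call_regions(sc_in,
                         threshold = rc$threshold %||% defaults$threshold,
                         max_gap = rc$max_gap %||% defaults$max_gap)
    art$regions <- file.path(outdir, "regions.bed")
    write_regions(regs, art$regions)
    params$regions <- list(threshold = rc$threshold %||% defaults$threshold,
                           max_gap = rc$max_gap %||% defaults$max_gap)
  }

  if ("de" %in% stages) {
    dc <- config$de %||% list()
    check_keys(dc, known_config_keys$de, "de")
    if (is.null(dc$fpkm)) stop("de stage needs de$fpkm (an FPKM table path)")
    fm <- read_fpkm(dc$fpkm)
    qc <- replicate_correlation(fm, floor = defaults$cor_floor)
    de <- select_de_genes(fm, fold = dc$fold %||% defaults$fold,
                          pseudocount = dc$pseudocount %||%
                            defaults$pseudocount)
    art$de_qc <- file.path(outdir, "replicate_qc.tsv")
    write_tsv(qc, art$de_qc)
    long <- do.call(rbind, lapply(names(de$per_time), function(tt) {
      d <- de$per_time[[tt]]
      if (nrow(d)) cbind(time = tt, d) else NULL
    }))
    art$de_sets <- file.path(outdir, "de_sets.tsv")
    write_tsv(long %||% data.frame(time = character(), gene = character(),
                                   log2_ratio = numeric(), sign = integer()),
              art$de_sets)
    art$de_union <- file.path(outdir, "de_union.txt")
    write_gene_list(de$union, art$de_union)
    params$de <- list(fold = dc$fold %||% defaults$fold,
                      pseudocount = dc$pseudocount %||% defaults$pseudocount)
  }

  if ("strata" %in% stages) {
    st <- config$strata %||% list()
    check_keys(st, known_config_keys$strata, "strata")
    if (is.null(st$hits) || is.null(st$taxa) || is.null(st$universe))
      stop("strata stage needs strata$hits, strata$taxa and strata$universe")
    ladder <- read_taxon_map(st$taxa,
                             strata = st$strata_order %||% default_strata())
    genes <- read_gene_list(st$universe)
    asg <- assign_phylostrata(genes, read_hits(st$hits), ladder,
                              e_max = st$e_max %||% defaults$e_max)
    art$strata <- file.path(outdir, "strata.tsv")
    write_tsv(asg, art$strata)
    art$strata_census <- file.path(outdir, "strata_census.tsv")
    write_tsv(stratum_census(asg, genes, ladder), art$strata_census)
    params$strata <- list(e_max = st$e_max %||% defaults$e_max)
  }

  if ("enrich" %in% stages) {
    ec <- config$enrich %||% list()
    check_keys(ec, known_config_keys$enrich, "enrich")
    if (is.null(ec$annot) || is.null(ec$universe))
      stop("enrich stage needs enrich$annot and enrich$universe")
    test_set <- if (!is.null(ec$set)) read_gene_list(ec$set)
    else if (!is.null(de)) de$union
    else stop("enrich stage needs the de stage or enrich$set")
    res <- enrich(test_set, read_annotations(ec$annot),
                  read_gene_list(ec$universe),
                  alpha = ec$alpha %||% defaults$alpha, m = ec$m)
    art$enrich <- file.path(outdir, "enrich.tsv")
    write_enrichment(res, art$enrich)
    params$enrich <- list(alpha = ec$alpha %||% defaults$alpha)
  }

  manifest <- list(
    package = "segscan",
    version = as.character(packageVersion("segscan")),
    parameters = params,
    outputs = lapply(art, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  art$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(art)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
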