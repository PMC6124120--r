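# Readers/writers for the tabular formats the pipeline touches. Internal
# coordinates are 1-based inclusive everywhere; the single conversion to
# 0-based half-open happens in the BED writer.

fmt_num <- function(x) {
  # full-precision numeric text so write -> read round-trips exactly
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", quote = "",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a two-pool allele-count table
#'
#' Reads per-SNP ref/alt allele counts for the unicellular- and
#' multicellular-enriched pools, either from the headered TSV schema
#' (`chrom, pos, ref, alt, refU, altU, refM, altM[, alt_origin]`) or from a
#' VCF whose two samples (named `U` and `M`, or taken in file order) carry
#' `AD` allele-depth fields. Multi-allelic VCF records are skipped with a
#' message. The returned table is validated and position-sorted.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return data.frame in the pool-counts schema, ready for [bsa_scan()].
#' @export
read_pool_counts <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    if (file.size(path) == 0 ||
        !length(readLines(path, n = 1, warn = FALSE))) {
      warning("empty pool-counts file: ", path)
      return(validate_pool_counts(data.frame(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), refU = integer(), altU = integer(),
        refM = integer(), altM = integer())))
    }
    x <- read_tsv(path)
    return(validate_pool_counts(x))
  }
  read_pool_counts_vcf(path)
}

read_pool_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multi-allelic VCF record(s) skipped")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || !ncol(ad))
    stop("VCF lacks per-sample AD (allele depth) fields")
  if (ncol(ad) != 2)
    stop("expected exactly two pool samples in the VCF, found ", ncol(ad))
  sm <- colnames(ad)
  iu <- if (all(c("U", "M") %in% sm)) match("U", sm) else 1L
  im <- if (all(c("U", "M") %in% sm)) match("M", sm) else 2L
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad & !multi))
      stop("malformed AD field at VCF data line ", which(bad & !multi)[1])
    list(ref = as.integer(vapply(parts, `[`, "", 1)),
         alt = as.integer(vapply(parts, function(p) p[min(2, length(p))],
                                 "")))
  }
  u <- split_ad(ad[, iu]); m <- split_ad(ad[, im])
  out <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    refU = u$ref, altU = u$alt, refM = m$ref, altM = m$alt
  )[!multi, , drop = FALSE]
  rownames(out) <- NULL
  validate_pool_counts(out)
}

#' Write a two-pool allele-count table
#'
#' @param counts pool-counts data.frame (or a `cross_sim`).
#' @param path output path.
#' @param format `"tsv"` (the headered schema) or `"vcf"` (VCF 4.2 with two
#'   samples `U` and `M` carrying `AD` fields).
#' @return `path`, invisibly.
#' @export
write_pool_counts <- function(counts, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (inherits(counts, "cross_sim")) counts <- counts$counts
  counts <- validate_pool_counts(counts)
  if (format == "tsv") return(write_tsv(counts, path))
  ref <- if ("ref" %in% names(counts)) counts$ref else "A"
  alt <- if ("alt" %in% names(counts)) counts$alt else "C"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("##contig=<ID=", unique(counts$chrom), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "U", "M", sep = "\t"))
  body <- paste(counts$chrom, counts$pos, ".", ref, alt, ".", ".", ".",
                "AD", paste0(counts$refU, ",", counts$altU),
                paste0(counts$refM, ",", counts$altM), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a scan table
#'
#' Headered TSV with full-precision numerics, so `read_scan(write_scan(x))`
#' reproduces `x` exactly.
#'
#' @param scan a `bsa_scan`.
#' @param path file path.
#' @return `write_scan`: `path` invisibly; `read_scan`: a `bsa_scan`.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "bsa_scan"))
  write_tsv(as.data.frame(scan), path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  x <- read_tsv(path, colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "p_hat", "d_obs", "p_exact", "log_odds",
            "neg_log10_p", "direction")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("scan table lacks column(s): ", paste(miss, collapse = ", "))
  structure(x, class = c("bsa_scan", "data.frame"),
            min_depth = NA, sided = NA, conditional = NA, n_skipped = NA)
}

#' Write candidate regions as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention at this boundary only. Columns: chrom, start, end,
#' name (`peak:<pos>`), score (peak log odds).
#'
#' @param regions a `bsa_regions` from [call_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "bsa_regions"))
  lines <- if (nrow(regions)) {
    paste(regions$chrom, regions$start - 1L, regions$end,
          paste0("peak:", regions$peak_pos),
          fmt_num(regions$peak_log_odds), sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Write an enrichment table
#'
#' @param result an `enrichment_result` from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "enrichment_result"))
  write_tsv(as.data.frame(result), path)
}

#' Read an FPKM table
#'
#' Headered TSV, genes in rows (first column = gene id), sample columns
#' named `strain_time_replicate` (e.g. `evolved_9h_r2`).
#'
#' @param path file path.
#' @return An [fpkm_matrix].
#' @export
read_fpkm <- function(path) {
  x <- read_tsv(path)
  genes <- as.character(x[[1]])
  vals <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  fpkm_matrix(vals)
}

#' Read tabular homology hits
#'
#' Accepts a headered TSV with columns `qseqid`, `sseqid`, `evalue`,
#' `staxid` (extra columns kept), or a headerless four-column table in that
#' order — the shape of tabular protein-search output plus a subject-taxon
#' column.
#'
#' @param path file path.
#' @return data.frame of hits for [assign_phylostrata()].
#' @export
read_hits <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("qseqid", first, fixed = TRUE)) {
    x <- read_tsv(path)
  } else {
    x <- read.table(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
    if (ncol(x) < 4) stop("headerless hits need 4 columns: ",
                          "qseqid, sseqid, evalue, staxid")
    names(x)[1:4] <- c("qseqid", "sseqid", "evalue", "staxid")
  }
  x$evalue <- as.numeric(x$evalue)
  x
}

#' Read a taxon-to-stratum mapping table
#'
#' Two-column headered TSV (`taxon`, `stratum`).
#'
#' @param path file path.
#' @param strata ladder order (least inclusive first).
#' @return A [stratum_ladder].
#' @export
read_taxon_map <- function(path, strata = default_strata()) {
  stratum_ladder(strata, read_tsv(path))
}

#' Read / write a plain-text gene list
#'
#' One gene id per line; blank lines ignored.
#'
#' @param path file path.
#' @param genes character vector (for writing).
#' @return `read_gene_list`: character vector; `write_gene_list`: `path`.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a gene-to-category annotation table
#'
#' Two-column headered TSV (`gene`, `category`), the association-file shape
#' used for functional annotation.
#'
#' @param path file path.
#' @return data.frame for [enrich()].
#' @export
read_annotations <- function(path) {
  x <- read_tsv(path)
  if (!all(c("gene", "category") %in% names(x)))
    stop("annotation table needs columns: gene, category")
  x
}
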