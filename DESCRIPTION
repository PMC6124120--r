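Package: segscan
Title: Bulked Segregant Genome Scans, Expression Filters and Gene-Age
    Enrichment for Pooled Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a phenotype segregating in a haploid cross from
    pooled sequencing data. Implements an exact-binomial log-odds genome scan
    over two bulked segregant pools, candidate-region calling, a fold-change
    differential-expression filter with replicate-correlation quality control,
    phylostratum (gene-age) assignment from tabular homology hits, and a shared
    two-tailed hypergeometric over/underrepresentation engine with Bonferroni
    correction. A synthetic F2-cross and pooled-sequencing generator with known
    causal loci supports power analysis and end-to-end validation of every
    stage without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
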