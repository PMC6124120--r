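---
title: "Methods: pooled-cross genome scans and gene-set statistics in segscan"
author: "segscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-cross genome scans and gene-set statistics in segscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segscan)
```

# The problem

A haploid green alga (*Chlamydomonas reinhardtii*) that evolved a simple
multicellular life cycle under settling selection is crossed to a unicellular
strain. The F2 progeny segregate the multicellularity phenotype, and two
pools — one enriched for unicellular and one for multicellular segregants by
repeated growth and low-speed centrifugation — are sequenced in bulk. At
every SNP that distinguishes the two parents, the pooled read counts
estimate each pool's allele frequency; alleles linked to causal loci differ
in frequency between the pools, while unlinked alleles do not. Downstream,
RNA-seq contrasts between the evolved and ancestral strains feed a
fold-change filter, and the resulting gene sets are tested for
over/underrepresentation of gene-age classes (phylostrata) and functional
categories.

`segscan` implements the statistics of that workflow — the per-SNP exact
test, region calling, the expression filter, phylostratum assignment and the
enrichment engine — together with a generative model of the cross itself,
so every stage can be validated on data with known ground truth.

# The scan statistic

At a SNP, let $k_U$ of $n_U$ reads in the unicellular-enriched pool and
$k_M$ of $n_M$ reads in the multicellular-enriched pool carry the
alternate (multicellular-parent) allele. The null model conditions on the
*observed pooled frequency*

$$\hat p = \frac{k_U + k_M}{n_U + n_M},$$

and asks: if both pools were resequenced independently with
$K_U \sim \mathrm{Bin}(n_U, \hat p)$ and $K_M \sim \mathrm{Bin}(n_M, \hat p)$,
how probable is a frequency difference at least as large as the one
observed?

$$p = \Pr\bigl(\,|K_U n_M - K_M n_U| \ \ge\ |k_U n_M - k_M n_U|\,\bigr).$$

Conditioning on $\hat p$ rather than on the 1:1 Mendelian expectation is
deliberate: an allele that confers a growth advantage during the outgrowth
of the pools drifts in overall frequency in *both* pools, and a test
against 1:1 would flag it spuriously. A deviation *between* the pools, at
the frequency the pools jointly show, can only come from sampling error or
from the phenotype-based separation itself.

Implementation notes:

* Differences are compared as cross-multiplied integers
  ($k_U n_M$ vs $k_M n_U$), so tie handling is exact and
  platform-independent, and the observed outcome always counts: $p > 0$.
* The reported computation enumerates $K_U$ and uses the binomial CDF over
  $K_M$ — an $O(n_U)$ path that equals the full
  $O(n_U n_M)$ double enumeration to better than $10^{-12}$ (checked
  exhaustively for all depths $\le 30$ and on random deep instances in the
  test suite).
* The score plotted along the genome is
  $\log_{10}\bigl((1-p)/p\bigr)$: the log odds that the difference is not a
  chance fluctuation. Both $p$ and $1-p$ are floored at $10^{-300}$, so the
  score is finite everywhere and equals $-300$ when $p = 1$. A plain
  $-\log_{10} p$ column is emitted alongside. Base 10 is chosen for
  readability of genome-scan scales.
* The two-sided (magnitude) tail is the default, since both directions of
  enrichment are biologically meaningful; a one-sided tail
  (`sided = "greater"`) and a Fisher-style conditional null
  (`conditional = TRUE`, conditioning on $k_U + k_M$) are available for
  sensitivity analysis.
* SNPs with fewer than `min_depth = 10` reads in either pool are skipped:
  the exact test is valid at any depth but nearly powerless below ~10
  reads, and shallow sites inflate the multiple-testing burden.

Candidate regions are called by merging above-threshold SNPs within
`max_gap` (default 500 kb) on a chromosome; regions are ranked by their
peak score with ties broken leftmost. The default threshold of 3 log-odds
units (roughly $p < 10^{-3}$) was fixed by pilot simulation: at the default
study design it keeps isolated false positives to a handful of single-SNP
regions per genome while the causal regions score 15–20.

# The generative model of the cross

`simulate_cross()` is a first-class, tested model — not a fixture. Its
defaults are the study conditions wherever those are stated, and
conventional choices where they are not:

| Parameter | Default | Why |
|---|---|---|
| chromosomes | 17 × 1 Morgan, 5 Mb | karyotype of *C. reinhardtii*; 1 M per chromosome is a conventional genetic length |
| markers | 20 per chromosome, evenly spaced | desk-scale marker density (340 genome-wide) |
| pool depths | 155× / 128× | the sequenced coverages of the unicellular / multicellular pools |
| `n_f2` | 2000 | the cross is described only as a "large pool" of F2s; 2000 is realistic for a bulk mating and is surfaced as a parameter, not a constant |
| `n_f1` | 200 | same status as `n_f2` |
| `misclass_rate` | 0.05 | the repeated growth–centrifugation enrichment is collapsed into a single per-individual missorting probability; 5% represents a good but imperfect separation |
| `seq_error_rate` | 0.002 | typical short-read per-base error after filtering |

Modelling decisions:

* **Meiosis** uses a Poisson crossover count per chromosome (mean = genetic
  length in Morgans, i.e. no interference) with uniform crossover positions
  — Haldane's model, chosen because it is standard and yields closed-form
  recombination fractions $r = \tfrac12(1 - e^{-2d})$ that the tests verify
  against simulation.
* **F1/F2 structure**: F1 individuals are meiotic recombinants of the two
  parental genomes; each F2 is the meiotic product of a random pair of
  distinct F1 parents. For a marker pair at recombination fraction $r$, the
  F2 haplotype frequencies in the infinite-F1-pool limit are
  $(1-r)^2/2 + r/4$ for parental and $r(1-r)/2 + r/4$ for recombinant
  haplotypes; the tests check this closed form with an F1 pool large enough
  that each parent is effectively used once. With a finite F1 pool the
  expectations are unchanged but sampling variance is inflated — tests that
  use binomial standard errors account for the extra layer.
* **Pool separation** is one stochastic sorting step: an individual joins
  the phenotype-matched pool with probability $1-\varepsilon$. The scan
  statistic only sees final pool composition, so $\varepsilon$ is the
  sufficient description of enrichment imperfection.
* **Sequencing**: per SNP, depth is Poisson (a negative-binomial size can
  be supplied for overdispersion); each read reports a uniformly random
  pool member's allele, flipped with the error probability — equivalently,
  the alternate count is binomial at
  $f(1-e) + (1-f)e$ for pool frequency $f$.
* **Growth during pooling**: optionally, carriers of a designated allele
  can be up-weighted in read sampling (a fitness multiplier), emulating the
  growth-rate confounder that motivates conditioning the test on $\hat p$.
  Off by default.
* **Null crosses**: with no causal locus configured, the population is
  split into two pools at random, since no genotype then determines
  settling.

What the generator does *not* emulate: linked selection during pool
outgrowth, depth correlation along chromosomes, reference-alignment bias,
variant-calling artifacts, or non-crossover gene conversion. Passing
recovery tests on this model therefore demonstrates the statistics are
correct and well calibrated under the stated design — not that any
particular real dataset is free of those upstream artifacts.

# The expression filter

Replicate agreement is summarised as Pearson's $r$ (and $r^2$) over genes
for every replicate pair within a (strain, time point) condition, with an
advisory flag below 0.98 — agreement is reported, not enforced.

A gene is differentially expressed at a time point when
$|\log_2(\bar x_{\mathrm{evolved}} / \bar x_{\mathrm{ancestor}})| \ge \log_2(\mathrm{fold})$,
means taken across replicates, fold defaulting to 4 ($\log_2 \ge 2$,
inclusive). The union across time points collects genes differential at one
or more time points; per-time-point sign is retained because a gene can be
overexpressed at one time point and underexpressed at another.

Zeros: FPKM values of 0 would make the ratio infinite. The pseudocount
(default 0.1 FPKM) is applied **only when one of the two means is zero** —
both means are then shifted by it. A global pseudocount would shrink every
ratio and silently exclude genes sitting exactly at the fold boundary
(e.g. means 40 vs 10 give $\log_2(40.1/10.1) = 1.989 < 2$); the
zero-rescue form keeps the boundary exact while making all ratios finite.
This inclusive-boundary behaviour is pinned by the test suite.

Statistical significance of differential expression is *not* re-tested
here (that belongs to count-based DE machinery upstream); an optional
significance mask lets users intersect the fold filter with upstream calls.

# Phylostrata and enrichment

Each gene's phylostratum is the most inclusive stratum among its homology
hits — the oldest taxonomic depth at which homology is detectable. The
default ladder is the eight nested strata for the volvocine algae:
*Chlamydomonas* < volvocine < Chlamydomonadales < Chlorophyceae <
Chlorophyta < Viridiplantae < Eukaryota < cellular organisms, with
"volvocine" meaning the *Chlamydomonas* + *Gonium* + *Volvox* clade. Hits
qualify when $E < 0.001$, strictly — a hit at exactly 0.001 is discarded.
Taxon-to-stratum resolution uses a supplied two-column table rather than a
live taxonomy service, for reproducibility. Two conventions the source
methods leave open, decided here and exposed as options: a gene with no
qualifying non-self hit is assigned the least-inclusive (lineage-specific)
stratum, and a hit whose subject id equals the query id is treated as the
query's own database record and dropped.

Enrichment of a gene set against any categorisation (strata or ontology
terms) uses the two-tailed hypergeometric test in its minimum-likelihood
form: the two-sided $p$ is the total probability of all feasible overlaps
no more probable than the observed one (with a $1+10^{-7}$ relative guard
against floating ties). Bonferroni correction multiplies by the number of
categories tested per run (the family size is an explicit argument, since
the original analyses' family is not recoverable), and significance is
called at $\alpha = 0.0025$ in replication mode. The effect-size score
mirrors the scan: $\mathrm{sign}(k/n - K/N) \cdot \log_{10}((1-p)/p)$, and
a plain frequency log-odds-ratio column is available as an option.

# Numerical and testing choices

* All integer comparisons in the exact tests are done on exact integers;
  products up to $300 \times 300$ are far below the double-precision
  integer limit.
* Tables are written with `%.17g` formatting so a write/read cycle is
  bit-exact; BED output is the single place 1-based inclusive coordinates
  become 0-based half-open.
* `run_pipeline()` derives all randomness from one seed and emits a
  manifest with parameters and MD5 checksums; repeated runs are
  byte-identical.
* Validation sizes: the oracle-equivalence tests are exhaustive over all
  count configurations with depths $\le 30$ (about 245,000 instances) and
  all hypergeometric instances with $N \le 40$, plus random deep instances;
  calibration uses 20 seeded null crosses of 5000 F2s; power uses 50
  seeded two-locus crosses of 2000 F2s. These sizes give the recovery
  proportions a resolution of 2% while keeping the default test run
  desk-scale.
* The Monte-Carlo agreement test compares the exact $p$ to $10^5$
  resequencing draws using the exact central binomial interval with the
  coverage of a $\pm 3\sigma$ band; for very small $p$ the normal band is
  ill-posed (expected hit counts below one) while the exact interval has
  the intended coverage at every $p$.

# A worked example

```{r example, eval = FALSE}
library(segscan)

cfg <- cross_config(
  genome = default_genome_map(),
  causal_loci = data.frame(chrom = c("chr14", "chr16"),
                           pos = c(2375000, 2375000)),
  phenotype_model = "ALL", misclass_rate = 0.05,
  n_f2 = 2000, seed = 3)
sim <- simulate_cross(cfg)
sc <- bsa_scan(sim)
summary(sc)
call_regions(sc, threshold = 3)
plot(sc, threshold = 3)
```

# Known limitations

* The scan is per-SNP; no smoothing or sliding-window statistic is
  provided, so single-SNP outliers can form spurious one-SNP regions at
  permissive thresholds.
* The exact test treats reads as independent draws from the pool; true
  pooled sequencing adds an individual-sampling layer whose extra variance
  is small at realistic pool sizes but makes the test marginally less
  conservative than nominal (the calibration tests bound this empirically).
* Phylostratum assignment inherits every bias of the homology search and
  the taxon sampling behind the mapping table; sparsely sequenced strata
  are unreliable, which is precisely why genome-wide stratum counts are
  treated as inputs, not reproducible outputs.
* Bonferroni control across categories is conservative for correlated
  categories (nested strata, overlapping ontology terms); no FDR
  alternative is offered because the replication target is familywise
  control.
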