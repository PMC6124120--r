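two_marker_map <- function(d_morgan) {
  genome_map(
    data.frame(chrom = "c1", length_bp = 1e6, length_morgan = 2 * d_morgan),
    data.frame(chrom = "c1", pos = c(25e4, 75e4)))
}

test_that("meiosis limits: no recombination and identical parents", {
  gm0 <- genome_map(
    data.frame(chrom = c("c1", "c2"), length_bp = 1e6, length_morgan = 0),
    data.frame(chrom = rep(c("c1", "c2"), each = 3),
               pos = rep(c(1e5, 5e5, 9e5), 2)))
  set.seed(1)
  a <- rep(1L, 6); b <- rep(0L, 6)
  for (i in 1:20) {
    off <- simulate_meiosis(a, b, gm0)
    # zero genetic length: each chromosome is wholly one parent
    expect_true(all(off[1:3] == off[1]))
    expect_true(all(off[4:6] == off[4]))
  }
  gm1 <- default_genome_map(n_chrom = 2, markers_per_chrom = 10)
  p <- rep(c(0L, 1L), 10)
  expect_identical(simulate_meiosis(p, p, gm1), p)
  expect_error(simulate_meiosis(p[1:5], p, gm1), "every marker")
})

test_that("parental-origin switch frequency follows Haldane's map function", {
  d <- 0.3                                 # Morgans between the two markers
  gm <- two_marker_map(d)
  n <- 1e4
  set.seed(21)
  off <- segscan:::meiosis_population(matrix(1L, n, 2), matrix(0L, n, 2), gm)
  sw <- mean(off[, 1] != off[, 2])
  r <- (1 - exp(-2 * d)) / 2
  expect_lt(abs(sw - r), 3 * sqrt(r * (1 - r) / n))
})

test_that("F2 population: Mendelian frequencies, determinism, linkage", {
  gm <- default_genome_map(n_chrom = 2, markers_per_chrom = 3)
  cfg <- cross_config(gm, n_f2 = 1e4, n_f1 = 1e5, seed = 5)
  g <- simulate_f2_population(cfg)
  freq <- colMeans(g == 1L)
  # SE of the estimator includes the finite F1 pool's sampling layer
  se <- sqrt(0.25 / 1e4 + 0.25 / 1e5)
  expect_true(all(abs(freq - 0.5) < 3 * se))
  expect_identical(g, simulate_f2_population(cfg))       # fixed seed

  # two tightly linked markers: haplotype frequencies match the
  # infinite-F1-pool closed form P(recombinant) = r(3/2 - r)/... terms
  d <- 0.01
  gm2 <- two_marker_map(d)
  cfg2 <- cross_config(gm2, n_f2 = 1e5, n_f1 = 2e5, seed = 11)
  g2 <- simulate_f2_population(cfg2)
  r <- (1 - exp(-2 * d)) / 2
  exp_same <- (1 - r)^2 / 2 + r / 4
  exp_rec <- r * (1 - r) / 2 + r / 4
  expv <- c(`00` = exp_same, `01` = exp_rec, `10` = exp_rec,
            `11` = exp_same)
  emp <- table(factor(paste0(g2[, 1], g2[, 2]),
                      names(expv))) / nrow(g2)
  se <- sqrt(expv * (1 - expv) / nrow(g2))
  expect_true(all(abs(as.numeric(emp) - expv) < 3 * se))
})

test_that("phenotype rules apply the causal-allele logic", {
  gm <- default_genome_map(n_chrom = 2, markers_per_chrom = 3)
  loci <- data.frame(chrom = c("chr01", "chr02"), pos = c(2500000, 2500000))
  cfg_all <- cross_config(gm, loci, phenotype_model = "ALL")
  cfg_any <- cross_config(gm, loci, phenotype_model = "ANY")
  both <- rep(1L, 6)
  one <- c(0L, 1L, 0L, 0L, 0L, 0L)   # derived at the chr01 causal locus only
  none <- rep(0L, 6)
  expect_equal(assign_phenotype(both, cfg_all), "multicellular")
  expect_equal(assign_phenotype(one, cfg_all), "unicellular")
  expect_equal(assign_phenotype(one, cfg_any), "multicellular")
  expect_equal(assign_phenotype(none, cfg_any), "unicellular")
  expect_error(
    cross_config(gm, data.frame(chrom = "chr01", pos = 123)),
    "not on a marker")
})

test_that("pool sorting: perfect, uninformative and analytic imperfect case", {
  phen <- rep(c("unicellular", "multicellular"), c(700, 300))
  set.seed(3)
  p0 <- select_pools(phen, 0)
  expect_identical(p0$U, 1:700)
  expect_identical(p0$M, 701:1000)

  # eps = 0.5: pool membership independent of phenotype
  gm <- default_genome_map(n_chrom = 2, markers_per_chrom = 3)
  loci <- data.frame(chrom = c("chr01", "chr02"), pos = c(2500000, 2500000))
  cfg <- cross_config(gm, loci, phenotype_model = "ALL", n_f2 = 1e4,
                      n_f1 = 5000, seed = 12)
  set.seed(12)
  g <- simulate_f2_population(cfg, reset_seed = FALSE)
  ph <- assign_phenotype(g, cfg)
  ci <- segscan:::marker_index(gm, "chr01", 2500000)
  ph_half <- select_pools(ph, 0.5)
  fU <- mean(g[ph_half$U, ci] == 1L); fM <- mean(g[ph_half$M, ci] == 1L)
  se <- sqrt(0.25 / length(ph_half$U)) + sqrt(0.25 / length(ph_half$M))
  expect_lt(abs(fU - fM), 3 * se)

  # eps = 0.1, ALL model over two unlinked loci: P(derived | pool M) =
  # (1/4) / ((1/4)(1-eps) + (3/4) eps), from the Mendelian class
  # frequencies and the misclassification mixture
  pools <- select_pools(ph, 0.1)
  fM <- mean(g[pools$M, ci] == 1L)
  expM <- 0.25 / (0.25 * 0.9 + 0.75 * 0.1)
  expect_lt(abs(fM - expM), 3 * sqrt(expM * (1 - expM) / length(pools$M)))
  expect_error(select_pools(phen, 1), "misclass_rate")
})

test_that("pooled read sampling matches its closed-form expectation", {
  gm <- default_genome_map(n_chrom = 1, markers_per_chrom = 1e4,
                           length_bp = 1e8)
  set.seed(8)
  # monomorphic derived pool, no error: every read reports alt
  mono <- matrix(1L, 5, 1e4)
  rd <- sample_pool_reads(mono, gm, mean_depth = 30)
  expect_true(all(rd$ref_count == 0))
  # saturated error: alt fraction 0.5 regardless of composition
  rd5 <- sample_pool_reads(mono, gm, mean_depth = 50, seq_error_rate = 0.5)
  frac <- sum(rd5$alt_count) / sum(rd5$alt_count + rd5$ref_count)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(rd5$alt_count + rd5$ref_count)))
  # mixed pool at frequency f, error e: mean alt fraction f(1-e) + (1-f)e
  f <- 0.3; e <- 0.01; lam <- 150
  pool <- rbind(matrix(1L, 3, 1e4), matrix(0L, 7, 1e4))
  rdm <- sample_pool_reads(pool, gm, mean_depth = lam, seq_error_rate = e)
  p_exp <- f * (1 - e) + (1 - f) * e
  tot <- sum(rdm$alt_count + rdm$ref_count)
  expect_lt(abs(sum(rdm$alt_count) / tot - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / tot))
  expect_error(sample_pool_reads(pool[0, , drop = FALSE], gm, 10), "empty")
})

test_that("simulate_cross is deterministic and carries its ground truth", {
  cfg <- cross_config(default_genome_map(n_chrom = 2),
                      data.frame(chrom = "chr01", pos = 2375000),
                      n_f2 = 300, seed = 42)
  s1 <- simulate_cross(cfg)
  s2 <- simulate_cross(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_equal(s1$truth$causal_loci$chrom, "chr01")
  expect_setequal(c(s1$pools$U, s1$pools$M), 1:300)
  expect_equal(sort(names(s1$counts)),
               sort(c("chrom", "pos", "ref", "alt", "refU", "altU",
                      "refM", "altM", "alt_origin")))
})

test_that("between-pool frequency differences decay with map distance", {
  gm <- default_genome_map(n_chrom = 1, markers_per_chrom = 20)
  acc <- 0
  for (s in 1:20) {
    sim <- simulate_cross(cross_config(
      gm, data.frame(chrom = "chr01", pos = 2375000),
      misclass_rate = 0.05, n_f2 = 1000, seed = 500 + s))
    sc <- suppressMessages(bsa_scan(sim, min_depth = 1))
    acc <- acc + abs(sc$d_obs)
  }
  md <- acc / 20
  dist <- abs(gm$markers$pos - 2375000)
  expect_lt(cor(dist, md, method = "spearman"), -0.8)
})

test_that("growth-locus fitness weighting shifts the sampled frequency", {
  gm <- default_genome_map(n_chrom = 1, markers_per_chrom = 100)
  pool <- rbind(matrix(1L, 5, 100), matrix(0L, 5, 100))
  set.seed(77)
  w <- c(rep(4, 5), rep(1, 5))   # derived carriers 4x more likely sampled
  rd <- sample_pool_reads(pool, gm, mean_depth = 200, weights = w)
  f_exp <- 20 / 25
  tot <- sum(rd$alt_count + rd$ref_count)
  expect_lt(abs(sum(rd$alt_count) / tot - f_exp),
            3 * sqrt(f_exp * (1 - f_exp) / tot))
})
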