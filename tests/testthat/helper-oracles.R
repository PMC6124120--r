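# Draw one element from a vector (safe for length-1 vectors, unlike sample()).
sample1 <- function(v) v[sample.int(length(v), 1L)]

# Independent brute-force oracles. These enumerate full outcome grids and are
# deliberately separate from the package's CDF-based code paths.

# Two independent binomials at the pooled frequency: exhaustive double
# enumeration of the (n_u + 1) x (n_m + 1) outcome grid.
oracle_exact_diff_p <- function(k_u, n_u, k_m, n_m) {
  phat <- (k_u + k_m) / (n_u + n_m)
  pu <- dbinom(0:n_u, n_u, phat)
  pm <- dbinom(0:n_m, n_m, phat)
  d <- abs(outer((0:n_m) * n_u, (0:n_u) * n_m, "-"))
  sum(outer(pm, pu)[d >= abs(k_m * n_u - k_u * n_m)])
}

# One-sided analogue (multicellular-pool excess at least as large).
oracle_exact_diff_p_greater <- function(k_u, n_u, k_m, n_m) {
  phat <- (k_u + k_m) / (n_u + n_m)
  pu <- dbinom(0:n_u, n_u, phat)
  pm <- dbinom(0:n_m, n_m, phat)
  t_all <- outer((0:n_m) * n_u, (0:n_u) * n_m, "-")
  sum(outer(pm, pu)[t_all >= k_m * n_u - k_u * n_m])
}

# Conditional (Fisher-style) variant: enumerate outcomes at fixed k_u + k_m.
oracle_exact_diff_p_conditional <- function(k_u, n_u, k_m, n_m) {
  s <- k_u + k_m
  ku <- max(0, s - n_m):min(s, n_u)
  w <- dhyper(ku, n_u, n_m, s)
  t_all <- (s - ku) * n_u - ku * n_m
  sum(w[abs(t_all) >= abs(k_m * n_u - k_u * n_m)])
}

# Minimum-likelihood two-sided hypergeometric tail by mass enumeration.
oracle_hypergeom_two <- function(N, K, n, k) {
  kk <- max(0, n + K - N):min(n, K)
  pr <- dhyper(kk, K, N - K, n)
  p0 <- pr[match(k, kk)]
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# Planted differential-expression fixture: 1000 genes, 100 truly at or above
# fourfold (one sitting exactly on the boundary, one with zero expression in
# the evolved strain), 900 below. Three noiseless replicates per condition so
# condition means are exact. Returns the matrix and the planted gene ids.
make_planted_fpkm <- function(seed = 1, n_genes = 1000, n_planted = 100) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  # 3-decimal base values survive a plain-text write/read exactly, so the
  # boundary gene stays exactly fourfold after a TSV round trip
  base <- round(runif(n_genes, 5, 50), 3)
  fold <- runif(n_genes, 1 / 3.5, 3.5)           # below fourfold
  planted <- sort(sample(n_genes, n_planted))
  f_pl <- runif(n_planted, 4.5, 30)
  f_pl <- ifelse(runif(n_planted) < 0.5, f_pl, 1 / f_pl)
  fold[planted] <- f_pl
  fold[planted[1]] <- 4                           # exact fourfold boundary
  evolved <- base * fold
  evolved[planted[2]] <- 0                        # zero-expression planted
  vals <- cbind(
    matrix(rep(base, 3), ncol = 3), matrix(rep(evolved, 3), ncol = 3),
    matrix(rep(base, 3), ncol = 3), matrix(rep(base, 3), ncol = 3)
  )
  colnames(vals) <- c(paste0("ancestor_3h_r", 1:3),
                      paste0("evolved_3h_r", 1:3),
                      paste0("ancestor_6h_r", 1:3),
                      paste0("evolved_6h_r", 1:3))
  rownames(vals) <- genes
  list(fpkm = fpkm_matrix(vals), planted = genes[planted])
}

# Random homology-hit table over a given taxon map, for property tests.
random_hit_table <- function(genes, taxa, max_hits = 6) {
  n <- sample(0:max_hits, length(genes), replace = TRUE)
  q <- rep(genes, n)
  if (!length(q))
    return(data.frame(qseqid = character(), sseqid = character(),
                      evalue = numeric(), staxid = character()))
  data.frame(
    qseqid = q,
    sseqid = paste0("subj", seq_along(q)),
    evalue = 10^runif(length(q), -180, 1),
    staxid = sample(taxa, length(q), replace = TRUE))
}

toy_taxon_map <- function() {
  data.frame(
    taxon = c("Cre", "Cinc", "Gpec", "Vcar", "Dsal", "Cvul", "Otau",
              "Atha", "Hsap", "Scer", "Ecol"),
    stratum = c("Chlamydomonas", "Chlamydomonas", "volvocine", "volvocine",
                "Chlamydomonadales", "Chlorophyceae", "Chlorophyta",
                "Viridiplantae", "Eukaryota", "Eukaryota",
                "cellular organisms"))
}
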