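test_that("two-tailed hypergeometric: degenerate and frozen cases", {
  expect_equal(hypergeom_two_tailed(30, 7, 30, 7), 1)   # n = N forces k = K
  expect_equal(hypergeom_two_tailed(30, 0, 10, 0), 1)   # empty category
  # frozen mass-enumeration value
  expect_equal(hypergeom_two_tailed(20, 5, 10, 5), 0.032507739938081,
               tolerance = 1e-12)
  expect_error(hypergeom_two_tailed(20, 5, 10, 6), "feasible")
  expect_error(hypergeom_two_tailed(20, 25, 10, 5), "0 <= K <= N")
})

test_that("implementation equals the enumeration oracle on random draws", {
  set.seed(201)
  for (i in 1:200) {
    N <- sample(2:150, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample1(max(0, n + K - N):min(n, K))
    expect_equal(hypergeom_two_tailed(N, K, n, k),
                 oracle_hypergeom_two(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("two-sided tail brackets the one-sided tails", {
  set.seed(202)
  for (i in 1:60) {
    N <- sample(5:100, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample1(max(0, n + K - N):min(n, K))
    p2 <- hypergeom_two_tailed(N, K, n, k)
    lower <- phyper(k, K, N - K, n)
    upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_gte(p2 + 1e-12, min(lower, upper))
    expect_lte(p2, 1)
  }
})

test_that("complementing the test set leaves the two-sided p unchanged", {
  set.seed(203)
  universe <- paste0("g", 1:40)
  for (i in 1:25) {
    test_set <- sample(universe, sample(1:39, 1))
    members <- sample(universe, sample(1:40, 1))
    ann <- data.frame(gene = members, category = "cat")
    ann_c <- data.frame(gene = setdiff(universe, members),
                        category = "cat")
    p1 <- enrich(test_set, ann, universe)$p_two
    has_cat_c <- length(setdiff(universe, members)) > 0
    if (has_cat_c) {
      p2 <- enrich(setdiff(universe, test_set), ann_c, universe)$p_two
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  }
})

test_that("Bonferroni adjustment and the alpha = 0.0025 significance rule", {
  expect_equal(bonferroni(0.001, 10), 0.01)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_error(bonferroni(1.5), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
  p <- runif(20)
  expect_true(all(bonferroni(p, 20) >= p))   # never decreases a p value
  # at the replication-mode level: 0.002 significant, 0.003 not
  expect_true(0.002 <= replication_defaults()$alpha)
  expect_false(0.003 <= replication_defaults()$alpha)
})

test_that("representation log odds: sign rule and frozen magnitude", {
  # proportional representation: exactly zero
  expect_equal(representation_log_odds(100, 10, 50, 5), 0)
  # overrepresentation at even odds has magnitude 0 with sign +
  expect_equal(representation_log_odds(100, 10, 50, 6, p_two = 0.5), 0)
  # frozen oracle value: p_two = 6.38038905168971e-09 -> magnitude 8.1952
  r <- representation_log_odds(1000, 100, 50, 20)
  expect_gt(r, 0)
  expect_equal(r, 8.195152836086153, tolerance = 1e-9)
  expect_lt(representation_log_odds(1000, 100, 50, 2), 0)
})

test_that("enrich: degenerate runs and a planted three-category fixture", {
  universe <- paste0("g", 1:50)
  ann <- data.frame(
    gene = c(paste0("g", 1:10), paste0("g", 11:30), paste0("g", 31:50)),
    category = rep(c("A", "B", "C"), c(10, 20, 20)))
  # test set = universe: every category at its genome frequency
  res_all <- enrich(universe, ann, universe)
  expect_true(all(res_all$p_two == 1))
  expect_true(all(!res_all$significant))

  # test set exactly category A: maximal overrepresentation of A
  res <- enrich(paste0("g", 1:10), ann, universe, alpha = 0.0025)
  a <- res[res$category == "A", ]
  expect_equal(a$k, 10)
  expect_equal(a$direction, "over")
  expect_equal(res$p_two, sort(res$p_two))           # ordered output
  expect_equal(attr(res, "m"), 3)                    # per-run family size
  for (j in seq_len(nrow(res)))
    expect_equal(res$p_two[j],
                 oracle_hypergeom_two(res$N[j], res$K[j], res$n[j],
                                      res$k[j]), tolerance = 1e-12)
  expect_equal(res$p_adj, pmin(1, 3 * res$p_two))

  expect_error(enrich(c("g1", "nope"), ann, universe), "outside")
  # optional frequency log odds column
  res_f <- enrich(paste0("g", 1:10), ann, universe, freq_log_odds = TRUE)
  expect_true("freq_log_odds" %in% names(res_f))
})
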