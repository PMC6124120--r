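small_fpkm <- function() {
  vals <- cbind(
    ancestor_3h_r1 = c(10, 5, 8, 0.5, 3),
    ancestor_3h_r2 = c(12, 5, 8, 0.7, 3),
    evolved_3h_r1  = c(44, 5, 2, 1.8, 0),
    evolved_3h_r2  = c(44, 5, 2, 1.8, 0),
    ancestor_6h_r1 = c(10, 5, 8, 0.6, 3),
    ancestor_6h_r2 = c(10, 5, 8, 0.6, 3),
    evolved_6h_r1  = c(10, 5, 8, 0.6, 3),
    evolved_6h_r2  = c(10, 5, 8, 0.6, 3))
  rownames(vals) <- paste0("g", 1:5)
  fpkm_matrix(vals)
}

test_that("fpkm_matrix parses sample names and validates the design", {
  m <- small_fpkm()
  expect_equal(m$samples$strain,
               rep(c("ancestor", "evolved", "ancestor", "evolved"),
                   each = 2))
  expect_equal(unique(m$samples$time), c("3h", "6h"))
  bad <- m$values; colnames(bad)[1] <- "weird"
  expect_error(fpkm_matrix(bad), "strain_time_replicate")
  neg <- m$values; neg[1, 1] <- -1
  expect_error(fpkm_matrix(neg), "non-negative")
  # a condition with a single replicate is rejected
  expect_error(fpkm_matrix(m$values[, -1]), ">= 2 replicates")
})

test_that("replicate correlation: identity, scale invariance, hand value", {
  v <- cbind(ancestor_3h_r1 = c(1, 4, 2, 8, 5),
             ancestor_3h_r2 = c(1, 4, 2, 8, 5),
             evolved_3h_r1 = c(2, 3, 7, 1, 9),
             evolved_3h_r2 = 2 * c(2, 3, 7, 1, 9))
  rownames(v) <- paste0("g", 1:5)
  rc <- suppressWarnings(replicate_correlation(fpkm_matrix(v)))
  expect_equal(rc$r[rc$strain == "ancestor"], 1)
  expect_equal(rc$r[rc$strain == "evolved"], 1)   # Pearson scale invariance

  # non-trivial pair: compare against the definitional formula
  v2 <- v; v2[, 2] <- c(2, 5, 1, 9, 4)
  x <- v2[, 1]; y <- v2[, 2]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rc2 <- suppressWarnings(replicate_correlation(fpkm_matrix(v2)))
  expect_equal(rc2$r[rc2$strain == "ancestor"], r_hand)
  expect_equal(rc2$r_squared[rc2$strain == "ancestor"], r_hand^2)
  expect_true(rc2$flagged[rc2$strain == "ancestor"])

  # constant replicate: undefined correlation is reported missing
  v3 <- v; v3[, 1] <- 7
  expect_warning(rc3 <- replicate_correlation(fpkm_matrix(v3)),
                 "constant")
  expect_true(is.na(rc3$r[1]))
})

test_that("mean log2 ratio: boundary, equality and zero handling", {
  m <- small_fpkm()
  lr <- mean_log2_ratio(m, pseudocount = 0.1)
  expect_equal(lr["g1", "3h"], 2)                     # 44 vs mean 11: exact
  expect_equal(lr["g2", "3h"], 0)
  expect_equal(lr["g5", "3h"], log2(0.1 / 3.1))      # zero-rescue
  expect_equal(lr[, "6h"], setNames(rep(0, 5), paste0("g", 1:5)))
  expect_error(mean_log2_ratio(m, pseudocount = 0), "pseudocount > 0")
})

test_that("fold selection is inclusive at the boundary and signed", {
  m <- small_fpkm()
  de <- select_de_genes(m, fold = 4)
  s3 <- de$per_time[["3h"]]
  expect_setequal(s3$gene, c("g1", "g3", "g5"))       # g1 exactly fourfold
  expect_equal(s3$sign[s3$gene == "g1"], 1L)
  expect_equal(s3$sign[s3$gene == "g3"], -1L)
  expect_equal(nrow(de$per_time[["6h"]]), 0)
  expect_setequal(de$union, c("g1", "g3", "g5"))
})

test_that("strain swap negates ratios and exchanges over/under sets", {
  m <- small_fpkm()
  v <- m$values
  colnames(v) <- sub("^ancestor", "TMP", colnames(v))
  colnames(v) <- sub("^evolved", "ancestor", colnames(v))
  colnames(v) <- sub("^TMP", "evolved", colnames(v))
  m2 <- fpkm_matrix(v)
  lr <- mean_log2_ratio(m); lr2 <- mean_log2_ratio(m2)
  expect_equal(lr2, -lr)
  de <- select_de_genes(m); de2 <- select_de_genes(m2)
  expect_setequal(de$union, de2$union)
  expect_equal(de$per_time[["3h"]]$sign,
               -de2$per_time[["3h"]]$sign[
                 match(de$per_time[["3h"]]$gene, de2$per_time[["3h"]]$gene)])
})

test_that("significance mask intersects with the fold filter", {
  m <- small_fpkm()
  mask <- matrix(TRUE, 5, 2, dimnames = list(paste0("g", 1:5),
                                             c("3h", "6h")))
  mask["g3", "3h"] <- FALSE
  de <- select_de_genes(m, mask = mask)
  expect_setequal(de$per_time[["3h"]]$gene, c("g1", "g5"))
  expect_error(select_de_genes(m, mask = mask[1:2, ]), "cover")
})

test_that("union equals genes differential at one or more time points", {
  fix <- make_planted_fpkm(seed = 4)
  de <- select_de_genes(fix$fpkm)
  per <- lapply(de$per_time, `[[`, "gene")
  expect_setequal(de$union, unique(unlist(per)))
  expect_lte(length(de$union), sum(lengths(per)))
})
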