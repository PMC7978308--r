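test_that("Fisher test matches hand cases and rejects bad tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1.0)
  res <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "positive")
  expect_error(fisher_exact_2x2(matrix(c(1, -1, 2, 2), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 2, 2), 2)), "integer")
  # odds-ratio conventions: cross-product, zero and Haldane-corrected
  expect_equal(fisher_exact_2x2(matrix(c(2, 4, 3, 6), 2))$odds_ratio, 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 4, 3, 6), 2))$odds_ratio, 0)
  hald <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2), haldane = TRUE)
  expect_equal(hald$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
})

test_that("Fisher p is invariant under transposition and row+column swaps", {
  set.seed(91)
  for (i in 1:25) {
    tab <- matrix(stats::rpois(4, 6), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(fisher_exact_2x2(t(tab))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_value, p, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches hand computation and is order-invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  p <- stats::runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pairwise tests call planted co-occurrence and exclusivity", {
  m <- matrix(FALSE, 2, 40, dimnames = list(c("GA", "GB"), NULL))
  m[, 1:20] <- TRUE  # identical mutated sets
  res <- pairwise_gene_tests(m)
  expect_equal(res$direction, "co_occurrent")
  expect_equal(res$p_value, fisher_p_oracle(matrix(c(20, 0, 0, 20), 2)),
               tolerance = 1e-9)
  m2 <- matrix(FALSE, 2, 40, dimnames = list(c("GA", "GB"), NULL))
  m2["GA", 1:20] <- TRUE; m2["GB", 21:40] <- TRUE
  expect_equal(pairwise_gene_tests(m2)$direction, "exclusive")
  expect_error(pairwise_gene_tests(m2, genes = c("GA", "GX")), "GX")
  expect_error(pairwise_gene_tests(m2[1, , drop = FALSE]), "2 genes")
})

test_that("pairwise FDR is controlled on independent genes", {
  set.seed(101)
  n <- 400; genes <- sprintf("G%02d", 1:10)
  m <- matrix(stats::runif(10 * n) < 0.25, 10, n, dimnames = list(genes, NULL))
  res <- pairwise_gene_tests(m)
  flagged <- mean(res$direction != "none")
  expect_lte(flagged, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("planted-effect directions are recovered with adequate power", {
  cfg <- btc_cohort_config(n_samples = 1500, seed = 47)
  g <- generate_cohort(cfg)
  ind <- mutation_indicator_matrix(g$cohort$variants,
                                   sample_ids = g$cohort$clinical$sample_id)
  res <- pairwise_gene_tests(ind[c("TP53", "CDKN2A", "ARID1A", "KRAS",
                                   "SMAD4", "LRP1B"), ])
  pick <- function(a, b) res[(res$gene_a == a & res$gene_b == b) |
                               (res$gene_a == b & res$gene_b == a), ]
  expect_equal(pick("TP53", "CDKN2A")$direction, "co_occurrent")
  expect_equal(pick("KRAS", "SMAD4")$direction, "co_occurrent")
  expect_equal(pick("TP53", "ARID1A")$direction, "exclusive")
  expect_equal(pick("KRAS", "LRP1B")$direction, "exclusive")
})

test_that("group comparison uses the Welch correction and handles edge cases", {
  res <- group_tmb_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  # one group constant: Welch still yields a finite statistic
  res2 <- group_tmb_test(c(5, 5, 5, 6, 7, 8), rep(c("a", "b"), each = 3))
  expect_true(is.finite(res2$t_statistic))
  expect_equal(unname(res2$t_statistic), (5 - 7) / sqrt(1 / 3),
               tolerance = 1e-9)
  # planted 2-SD shift is detected
  set.seed(3)
  x <- c(stats::rnorm(100), stats::rnorm(100, mean = 2))
  res3 <- group_tmb_test(x, rep(c("g1", "g2"), each = 100))
  expect_lt(res3$p_value, 0.001)
  expect_error(group_tmb_test(c(1, 2, 3), c("a", "a", "b")), "at least 2")
  expect_error(group_tmb_test(1:6, rep("a", 6)), "two groups")
})
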