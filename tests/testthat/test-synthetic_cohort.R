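test_that("generation is deterministic and n = 0 yields an empty cohort", {
  cfg <- btc_cohort_config(n_samples = 40, seed = 5)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(g1$cohort, d1); write_cohort(g2$cohort, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  g0 <- generate_cohort(btc_cohort_config(n_samples = 0, seed = 1))
  expect_equal(nrow(g0$cohort$clinical), 0)
  expect_equal(nrow(g0$truth$samples), 0)
})

test_that("planted gene frequencies are recovered within binomial error", {
  cfg <- btc_cohort_config(n_samples = 500, seed = 11)
  cfg$gene_freqs <- c(TP53 = 0.53)
  cfg$pair_effects <- list()
  g <- generate_cohort(cfg)
  obs <- mean(g$truth$gene_status["TP53", ])
  se <- sqrt(0.53 * 0.47 / 500)
  expect_lt(abs(obs - 0.53), 3 * se)
  # and the emitted variant table carries the same statuses
  ind <- mutation_indicator_matrix(g$cohort$variants,
                                   genes = "BRCA2",  # placeholder row check
                                   sample_ids = g$cohort$clinical$sample_id)
  tp53 <- mutation_indicator_matrix(g$cohort$variants, genes = "TP53",
                                    sample_ids = g$cohort$clinical$sample_id)
  expect_equal(unname(tp53["TP53", g$truth$samples$sample_id]),
               unname(g$truth$gene_status["TP53", ]))
})

test_that("pairwise tilting preserves the exact tilted marginals it reports", {
  cfg <- btc_cohort_config(n_samples = 4000, seed = 23)
  g <- generate_cohort(cfg)
  marg <- g$truth$gene_marginals
  for (gene in c("TP53", "CDKN2A", "KRAS", "ARID1A")) {
    obs <- mean(g$truth$gene_status[gene, ])
    se <- sqrt(marg[[gene]] * (1 - marg[[gene]]) / 4000)
    expect_lt(abs(obs - marg[[gene]]), 3.5 * se, label = gene)
  }
  # co-occurrence direction matches the planted log-odds sign
  tab <- table(g$truth$gene_status["TP53", ], g$truth$gene_status["CDKN2A", ])
  expect_gt(tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1]), 1)
  tab <- table(g$truth$gene_status["TP53", ], g$truth$gene_status["ARID1A", ])
  expect_lt(tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1]), 1)
})

test_that("channel sampling follows the planted mixture", {
  prof <- synthetic_reference_signatures()[, c("SBS1_like", "SBS22_like")]
  # point mass: single profile concentrated on one channel
  pm <- matrix(0, 96, 1); pm[8, 1] <- 1; rownames(pm) <- sbs_channels()
  expect_equal(unique(sample_mutation_channels(pm, 1, 50, seed = 1)), 7)
  expect_equal(sample_mutation_channels(prof, c(0.5, 0.5), 0), integer(0))
  # law of large numbers: empirical frequencies approach the mixture
  expo <- c(0.3, 0.7)
  draws <- sample_mutation_channels(prof, expo, 1e5, seed = 2)
  emp <- tabulate(draws + 1, nbins = 96) / 1e5
  expect_lt(max(abs(emp - as.vector(prof %*% expo))), 0.005)
  expect_error(sample_mutation_channels(prof, c(0.4, 0.4), 10), "probability")
})

test_that("outcome simulation honors its specification", {
  spec <- btc_cohort_config(seed = 1)$outcome_spec
  spec$responder_frac <- 0
  out <- simulate_outcomes(sprintf("P%d", 1:200), spec, seed = 3)
  expect_false(any(out$best_response %in% c("CR", "PR")))

  spec$pfs1_missing_frac <- 1
  out <- simulate_outcomes(sprintf("P%d", 1:50), spec, seed = 4)
  expect_true(all(is.na(out$pfs1_months)))
  ben <- pfs_ratio_benefit(out)
  expect_true(all(is.na(ben$outcomes$benefit)))
  expect_equal(ben$n_ratio_defined, 0)

  # Kaplan-Meier median of a large simulated sample matches the planted one
  spec <- btc_cohort_config(seed = 1)$outcome_spec
  spec$censor_frac <- 0.2
  out <- simulate_outcomes(sprintf("P%d", 1:10000), spec, seed = 5)
  km <- km_estimate(out$pfs2_months, out$pfs2_event)
  expect_gt(km$median, 4.8)
  expect_lt(km$median, 5.2)
})

test_that("config validation flags structural errors and implausible settings", {
  cfg <- btc_cohort_config(seed = 1)
  cfg$seed <- NULL
  expect_error(validate_cohort_config(cfg), "seed")
  cfg <- btc_cohort_config(seed = 1)
  cfg$subtype_props <- c(ICC = 0.5, ECC = 0.2, GBC = 0.2)
  expect_error(validate_cohort_config(cfg), "sum to 1")
  cfg <- btc_cohort_config(seed = 1)
  cfg$hypermutated_frac <- 0.9
  expect_warning(validate_cohort_config(cfg), "hypermutated_frac")
})
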