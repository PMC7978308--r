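test_that("the channel axis is the fixed 96-channel COSMIC ordering", {
  ch <- sbs_channels()
  expect_length(ch, 96)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
  expect_true(assert_channel_axis(ch))
  expect_error(assert_channel_axis(rev(ch)), "ordering")
  ra <- channel_ref_alt(c(0, 95))
  expect_equal(ra$ref, c("C", "T"))
  expect_equal(ra$alt, c("A", "G"))
})

test_that("catalogs tally context channels per sample and respect filters", {
  v <- data.frame(sample_id = c("A", "A", "B", "B"),
                  gene = "G", chrom = "1", pos = 1:4, ref = "C", alt = "T",
                  variant_class = "missense", vaf = 0.2,
                  context_channel = c(33, 33, 7, NA),
                  stringsAsFactors = FALSE)
  v$ref[4] <- "CA"  # indel row: channel legitimately missing
  m <- build_context_matrix(v)
  expect_equal(dim(m), c(96L, 2L))
  expect_equal(unname(m[34, "A"]), 2L)
  expect_equal(unname(m[8, "B"]), 1L)
  expect_equal(sum(m), 3)
  expect_equal(attr(m, "n_skipped"), 1L)
  # excluded sample disappears from the columns
  m2 <- build_context_matrix(v, drop_samples = "A")
  expect_equal(colnames(m2), "B")
  # a known histogram is reproduced exactly
  set.seed(41)
  chans <- sample(0:95, 1000, replace = TRUE)
  vv <- data.frame(sample_id = "S", gene = "G", chrom = "1",
                   pos = seq_along(chans), ref = "C", alt = "T",
                   variant_class = "missense", vaf = 0.2,
                   context_channel = chans, stringsAsFactors = FALSE)
  expect_equal(unname(build_context_matrix(vv)[, 1]),
               tabulate(chans + 1, nbins = 96))
  expect_warning(build_context_matrix(v[0, ], sample_ids = "Z"), "empty")
})

test_that("KL-NMF recovers exact low-rank structure", {
  prof <- synthetic_reference_signatures()[, "SBS22_like", drop = FALSE]
  loads <- c(200, 500, 120, 340)
  V <- prof %*% rbind(loads)  # exact rank-1, continuous counts
  rownames(V) <- sbs_channels()
  fit <- nmf_decompose(V, k = 1, seed = 3, n_init = 5)
  expect_gt(cosine_similarity(fit$profiles[, 1], prof[, 1]), 0.999)
  expect_equal(colSums(fit$profiles), c(signature_1 = 1), tolerance = 1e-9)
  expect_true(all(fit$exposures >= 0))
  expect_equal(unname(colSums(fit$exposures)), loads, tolerance = 0.02)
  # k = S = 1: the profile is the normalized column
  v1 <- V[, 1, drop = FALSE]
  fit1 <- nmf_decompose(v1, k = 1, seed = 1, n_init = 3)
  expect_equal(unname(fit1$profiles[, 1]), unname(v1[, 1] / sum(v1)),
               tolerance = 1e-6)
  expect_error(nmf_decompose(matrix(0, 96, 3), 1), "zero")
  expect_error(nmf_decompose(V, k = 5), "k must")
})

test_that("NMF fits are deterministic given the seed", {
  pc <- planted_catalog(n_samples = 30, seed = 19)
  f1 <- nmf_decompose(pc$catalog, k = 2, seed = 7, n_init = 3, max_iter = 300)
  f2 <- nmf_decompose(pc$catalog, k = 2, seed = 7, n_init = 3, max_iter = 300)
  expect_identical(f1$profiles, f2$profiles)
  expect_identical(f1$reconstruction_error, f2$reconstruction_error)
})

test_that("cosine similarity is symmetric, scale-invariant and bounded", {
  set.seed(12)
  for (i in 1:20) {
    u <- stats::runif(96); v <- stats::runif(96)
    cs <- cosine_similarity(u, v)
    expect_gte(cs, 0); expect_lte(cs, 1)
    expect_equal(cs, cosine_similarity(v, u))
    expect_equal(cs, cosine_similarity(3.7 * u, 0.2 * v), tolerance = 1e-12)
  }
  e1 <- c(1, rep(0, 95)); e2 <- c(0, 1, rep(0, 94))
  expect_equal(cosine_similarity(e1, e1), 1.0)
  expect_equal(cosine_similarity(e1, e2), 0.0)
  expect_error(cosine_similarity(e1, rep(0, 96)), "zero-norm")
})

test_that("cosine matching finds the generating reference", {
  ref <- synthetic_reference_signatures()
  m <- cosine_match(ref[, c("SBS22_like", "SBS1_like")], ref)
  expect_equal(m$reference, c("SBS22_like", "SBS1_like"))
  expect_equal(m$cosine, c(1, 1), tolerance = 1e-12)
})

test_that("rank selection handles trivial and degenerate ranges", {
  pc <- planted_catalog(n_samples = 40, seed = 29)
  sel <- select_rank(pc$catalog, k_range = 2, n_restarts = 4, seed = 1,
                     max_iter = 300)
  expect_equal(sel$k, 2L)
  # rank-1 catalog: higher ranks bring no real objective improvement
  prof <- pc$profiles[, 1, drop = FALSE]
  V1 <- vapply(1:30, function(i)
    tabulate(sample_mutation_channels(prof, 1, 250) + 1, nbins = 96),
    numeric(96))
  rownames(V1) <- sbs_channels()
  sel1 <- select_rank(V1, 1:3, n_restarts = 6, seed = 2, max_iter = 400)
  expect_equal(sel1$k, 1L)
  expect_warning(sel_deg <- select_rank(V1[, 1, drop = FALSE], 2:3,
                                        n_restarts = 2, seed = 1),
                 "degenerate")
  expect_equal(sel_deg$k, 2L)
})

test_that("exposure re-fitting recovers known mixture weights", {
  prof <- synthetic_reference_signatures()[, c("SBS1_like", "SBS22_like",
                                               "SBS40_like")]
  H_true <- rbind(c(120, 10), c(0, 300), c(80, 40))
  V <- prof %*% H_true
  H <- fit_exposures(V, prof, max_iter = 5000, tol = 1e-12)
  expect_equal(unname(H), unname(H_true), tolerance = 0.05)
})

test_that("attribution flags planted target samples and rejects bad inputs", {
  prof <- synthetic_reference_signatures()[, c("SBS1_like", "SBS22_like",
                                               "SBS40_like")]
  ss <- as_signature_set(prof)
  set.seed(55)
  V_pos <- vapply(1:6, function(i)
    tabulate(sample_mutation_channels(prof, c(0, 1, 0), 200) + 1, nbins = 96),
    numeric(96))
  rownames(V_pos) <- sbs_channels()
  att <- attribute_signature(V_pos, ss, target_index = 2, n_null = 200,
                             seed = 6)
  expect_true(all(att$positive))
  expect_true(all(att$exposure_fraction > 0.8))
  expect_true(all(att$p_value > 0 & att$p_value <= 1))
  expect_true(all(att$q_value >= att$p_value - 1e-12))
  expect_error(attribute_signature(V_pos, ss, 2, n_null = 0), "n_null")
  expect_warning(attribute_signature(V_pos[, 1, drop = FALSE], ss, 2,
                                     n_null = 50, seed = 1), "unstable")
  expect_error(attribute_signature(V_pos, as_signature_set(prof[, 1, drop = FALSE]),
                                   1, n_null = 200), "at least 2")
})

test_that("the shipped reference fixture matches the in-code catalog", {
  path <- system.file("extdata", "synthetic_reference_signatures.tsv",
                      package = "btcprof")
  ref <- read_signature_reference(path)
  expect_equal(ref, synthetic_reference_signatures(), tolerance = 1e-5)
  expect_equal(unname(colSums(ref)), rep(1, 5), tolerance = 1e-9)
})
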