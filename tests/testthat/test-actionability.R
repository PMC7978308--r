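kb_default <- load_knowledge_base()

one_clinical <- function(msi = FALSE, egfr_ihc = FALSE) {
  data.frame(sample_id = "P1", subtype = "ICC", stage = "II",
             hepatitis = "negative", platform = "TPS", msi_high = msi,
             egfr_ihc_2plus = egfr_ihc, germline_pathogenic_genes = "",
             stringsAsFactors = FALSE)
}

no_alt <- function() list(v = empty_cohort_table("variants"),
                          c = empty_cohort_table("copy_number"),
                          f = empty_cohort_table("fusions"))

test_that("the shipped knowledge base names 19 PAT genes plus MSI-H", {
  expect_equal(attr(kb_default, "n_pat_genes"), 19L)
  expect_true("MSI-H" %in% kb_default$target)
  expect_true(any(!kb_default$is_pat))  # the deliberate off-PAT entry
  # is_pat is consistent with the tier thresholds on every entry
  expect_equal(kb_default$is_pat,
               kb_default$oncokb_level %in% c("L1", "L2", "L3A") |
                 kb_default$escat_tier %in% c("IA", "IB", "IC", "IIA", "IIB"))
})

test_that("knowledge-base validation rejects malformed entries", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- target: XYZ", "  alteration_class: fusion",
               "  oncokb_level: none", "  escat_tier: none"), f)
  expect_error(load_knowledge_base(f), "neither")
  writeLines(c("- target: XYZ", "  alteration_class: fusion",
               "  oncokb_level: L1",
               "- target: XYZ", "  alteration_class: fusion",
               "  escat_tier: IA"), f)
  expect_error(load_knowledge_base(f), "duplicate")
  writeLines(c("- target: XYZ", "  alteration_class: odd_thing",
               "  oncokb_level: L1"), f)
  expect_error(load_knowledge_base(f), "alteration_class")
  writeLines(character(0), f)
  expect_warning(kb0 <- load_knowledge_base(f), "empty")
  expect_equal(nrow(kb0), 0)
})

test_that("annotation matches alterations by class, flag and locus", {
  a <- no_alt()
  # MSI-H flag + ERBB2 amplification -> two calls
  cn <- data.frame(sample_id = "P1", gene = "ERBB2",
                   cna_type = "amplification", cytoband = NA_character_,
                   stringsAsFactors = FALSE)
  calls <- annotate_patient(a$v, cn, a$f, one_clinical(msi = TRUE), kb_default)
  expect_setequal(calls$target, c("ERBB2", "MSI-H"))
  # no MSI flag -> amplification only
  calls2 <- annotate_patient(a$v, cn, a$f, one_clinical(), kb_default)
  expect_equal(calls2$target, "ERBB2")
  # synonymous variant in a PAT gene matches nothing
  v_syn <- data.frame(sample_id = "P1", gene = "IDH1", chrom = "2",
                      pos = 100, ref = "C", alt = "T",
                      variant_class = "synonymous", vaf = 0.4,
                      context_channel = 39, stringsAsFactors = FALSE)
  expect_equal(nrow(annotate_patient(v_syn, a$c, a$f, one_clinical(),
                                     kb_default)), 0)
  # fusion call, matching either partner
  fu <- data.frame(sample_id = "P1", gene_5p = "AHCYL1", gene_3p = "FGFR2",
                   stringsAsFactors = FALSE)
  calls3 <- annotate_patient(a$v, a$c, fu, one_clinical(), kb_default)
  expect_equal(calls3$target, "FGFR2")
  expect_equal(calls3$alteration_class, "fusion")
  # locus window: entries with pos_range only match inside it
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- target: EGFR", "  alteration_class: activating_mutation",
               "  oncokb_level: L3A", "  pos_range: [100, 200]"), f)
  kb_rng <- load_knowledge_base(f)
  v_in <- v_syn; v_in$gene <- "EGFR"; v_in$variant_class <- "missense"
  v_in$pos <- 150
  expect_equal(nrow(annotate_patient(v_in, a$c, a$f, one_clinical(), kb_rng)), 1)
  v_out <- v_in; v_out$pos <- 500
  expect_equal(nrow(annotate_patient(v_out, a$c, a$f, one_clinical(), kb_rng)), 0)
})

test_that("off-PAT calls are hidden unless requested", {
  a <- no_alt()
  cn <- data.frame(sample_id = "P1", gene = "CDKN2A", cna_type = "deletion",
                   cytoband = NA_character_, stringsAsFactors = FALSE)
  expect_equal(nrow(annotate_patient(a$v, cn, a$f, one_clinical(), kb_default)), 0)
  off <- annotate_patient(a$v, cn, a$f, one_clinical(), kb_default,
                          include_off_pat = TRUE)
  expect_equal(off$target, "CDKN2A")
  expect_false(off$is_pat)
})

test_that("MTB prioritization follows rules I-III deterministically", {
  a <- no_alt()
  cn <- data.frame(sample_id = "P1", gene = "ERBB2",
                   cna_type = "amplification", cytoband = NA_character_,
                   stringsAsFactors = FALSE)
  cl <- one_clinical(msi = TRUE)
  calls <- annotate_patient(a$v, cn, a$f, cl, kb_default)
  # rule II with the merged scale: ESCAT I-C (MSI-H) outranks OncoKB L2
  top <- prioritize(calls, cl)$top
  expect_equal(top$target, "MSI-H")
  # independence of irrelevant alternatives at rank 1
  top2 <- prioritize(calls[calls$target != "ERBB2", ], cl)$top
  expect_equal(top2$target, top$target)
  # rule III: EGFR requires IHC 2+/3+
  v_egfr <- data.frame(sample_id = "P1", gene = "EGFR", chrom = "7",
                       pos = 100, ref = "C", alt = "T",
                       variant_class = "missense", vaf = 0.3,
                       context_channel = 39, stringsAsFactors = FALSE)
  calls_e <- annotate_patient(v_egfr, a$c, a$f, one_clinical(), kb_default)
  expect_equal(calls_e$target, "EGFR")
  expect_null(prioritize(calls_e, one_clinical(egfr_ihc = FALSE))$top)
  expect_equal(prioritize(calls_e, one_clinical(egfr_ihc = TRUE))$top$target,
               "EGFR")
  # empty input
  expect_null(prioritize(calls_e[0, ], cl)$top)
  # total deterministic order: repeated calls give identical ordering
  o1 <- prioritize(calls, cl)$ordered
  o2 <- prioritize(calls, cl)$ordered
  expect_identical(o1, o2)
})

test_that("PAT prevalence counts patients, not calls", {
  cl <- data.frame(sample_id = c("A", "B", "C"),
                   subtype = c("ICC", "ICC", "GBC"), stage = "II",
                   hepatitis = "negative", platform = "TPS",
                   msi_high = FALSE, egfr_ihc_2plus = FALSE,
                   germline_pathogenic_genes = "", stringsAsFactors = FALSE)
  mkcall <- function(pid, tg) data.frame(
    patient_id = pid, target = tg, alteration_class = "amplification",
    oncokb_level = "L2", escat_tier = "none", merged_rank = 5,
    is_pat = TRUE, drug_hint = "", stringsAsFactors = FALSE)
  calls <- list(A = rbind(mkcall("A", "ERBB2"), mkcall("A", "MET")),
                B = mkcall("B", "MET")[0, ],
                C = mkcall("C", "MET"))
  sm <- summarize_pat_prevalence(calls, cl)
  expect_equal(sm$n_ge1_pat, 2)
  expect_equal(sm$n_ge2_pat, 1)
  expect_equal(sm$ge1_percent, 66.7)
  expect_equal(sm$per_target$n_patients[sm$per_target$target == "MET"], 2)
  expect_equal(sm$per_subtype$n_ge1_pat[sm$per_subtype$subtype == "ICC"], 1)
  # all-empty case
  sm0 <- summarize_pat_prevalence(list(A = calls$B, B = calls$B), cl[1:2, ])
  expect_equal(sm0$n_ge1_pat, 0)
  expect_equal(nrow(sm0$per_target), 0)
})

test_that("planted per-target prevalence is recovered by annotation", {
  cfg <- btc_cohort_config(n_samples = 1000, seed = 61)
  g <- generate_cohort(cfg)
  cl <- g$cohort$clinical
  v_by <- split(g$cohort$variants, factor(g$cohort$variants$sample_id,
                                          levels = cl$sample_id))
  c_by <- split(g$cohort$copy_number, factor(g$cohort$copy_number$sample_id,
                                             levels = cl$sample_id))
  f_by <- split(g$cohort$fusions, factor(g$cohort$fusions$sample_id,
                                         levels = cl$sample_id))
  calls <- lapply(seq_len(nrow(cl)), function(i)
    annotate_patient(v_by[[i]], c_by[[i]], f_by[[i]], cl[i, , drop = FALSE],
                     kb_default))
  names(calls) <- cl$sample_id
  sm <- summarize_pat_prevalence(calls, cl)
  # the annotation engine recovers exactly the planted carrier flags
  expect_equal(sm$n_ge1_pat, sum(g$truth$samples$pat_carrier))
  ps <- cfg$pat_spec
  for (tg in c("MET", "ERBB2", "IDH1")) {
    p <- ps$freq[ps$target == tg]
    obs <- sm$per_target$n_patients[sm$per_target$target == tg] / 1000
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 1000), label = tg)
  }
})
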