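#' @title End-to-end cohort pipeline and summary report
#' @name cohort_pipeline
NULL

#' Format named numerator/denominator pairs as percents
#'
#' Half-up one-decimal rounding; in report-style display a percent that
#' rounds to a whole number is printed without the decimal (96/803 ->
#' "12%").
#'
#' @param counts Named list, each element `c(numerator, denominator)` with
#'   denominator > 0.
#' @param report_style Drop the trailing ".0" in the display string.
#' @return Data frame with `name`, `numerator`, `denominator`, `percent`,
#'   `display`.
#' @export
summarize_counts <- function(counts, report_style = TRUE) {
  if (any(vapply(counts, function(x) x[2] <= 0, logical(1))))
    stop("denominators must be positive", call. = FALSE)
  pct <- vapply(counts, function(x) percent_half_up(x[1], x[2]), 1.0)
  disp <- vapply(pct, function(p) {
    if (report_style && abs(p - round(p)) < 1e-9)
      sprintf("%d%%", as.integer(round(p)))
    else sprintf("%.1f%%", p)
  }, character(1))
  data.frame(name = names(counts),
             numerator = vapply(counts, `[`, 1.0, 1),
             denominator = vapply(counts, `[`, 1.0, 2),
             percent = unname(pct), display = unname(disp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default pipeline options
#'
#' @param wes_mb,tps_mb Sequenced region sizes per platform (Mb); both
#'   mandatory knobs with the package defaults 38 (exome) and 1.5 (panel).
#' @param k Number of signatures, or `"auto"` for [select_rank()].
#' @param k_range Candidate ranks when `k = "auto"`.
#' @param n_init NMF restarts.
#' @param n_null Attribution null resamples.
#' @param fdr FDR level for attribution and pairwise tests.
#' @param min_gene_freq Mutation frequency above which a gene enters the
#'   pairwise co-occurrence screen.
#' @param reference Reference signature matrix (96 x R); defaults to the
#'   shipped synthetic toy catalog.
#' @param target_reference Reference name whose best-matching fitted
#'   profile is attributed per sample (the AA/SBS22-like pattern).
#' @param min_catalog_mutations Samples with fewer context mutations than
#'   this are excluded from signature extraction (panel samples carry too
#'   few SBS calls to inform a 96-channel fit).
#' @return Options list for [run_pipeline()].
#' @export
pipeline_options <- function(wes_mb = 38, tps_mb = 1.5, k = 3L,
                             k_range = 2:4, n_init = 20L, n_null = 200L,
                             fdr = 0.05, min_gene_freq = 0.05,
                             reference = synthetic_reference_signatures(),
                             target_reference = "SBS22_like",
                             min_catalog_mutations = 20L) {
  list(wes_mb = wes_mb, tps_mb = tps_mb, k = k, k_range = k_range,
       n_init = n_init, n_null = n_null, fdr = fdr,
       min_gene_freq = min_gene_freq, reference = reference,
       target_reference = target_reference,
       min_catalog_mutations = min_catalog_mutations)
}

#' Run the full cohort analysis pipeline
#'
#' Stages in dependency order: mutation burden and hypermutation calling;
#' signature extraction on the non-hypermutated ICC exome subset (the
#' subset with enough substitutions for a 96-channel fit), cosine matching
#' and per-sample attribution of the target (AA-like) signature at FDR
#' `fdr`; pairwise gene co-occurrence tests; DDR classification; per-
#' patient actionability annotation with MTB prioritization; therapy-
#' outcome evaluation when an outcomes table is present. Deterministic
#' given `seed`.
#'
#' @param cohort A validated `btc_cohort` with at least one sample.
#' @param opts Options list from [pipeline_options()].
#' @param seed Master integer seed; stage seeds are derived from it by
#'   fixed offsets so stages are independently reproducible.
#' @param out_dir Optional directory: per-stage TSV artifacts and the JSON
#'   summary are written there.
#' @return List of class `cohort_summary` with per-stage results
#'   (`tmb`, `signatures`, `attribution`, `pairwise`, `ddr`,
#'   `actionability`, `outcomes`) and `summary` (the headline
#'   count/percent table).
#' @export
run_pipeline <- function(cohort, opts = pipeline_options(), seed = 1L,
                         out_dir = NULL) {
  validate_cohort(cohort)
  cl <- cohort$clinical
  if (nrow(cl) == 0) stop("no samples", call. = FALSE)
  seed <- as.integer(seed)

  # --- stage 1: mutation burden -------------------------------------------
  mb <- c(WES = opts$wes_mb, TPS = opts$tps_mb)[cl$platform]
  names(mb) <- cl$sample_id
  tmb <- compute_tmb(cohort$variants, mb, sample_ids = cl$sample_id)
  tmb$platform <- cl$platform[match(tmb$sample_id, cl$sample_id)]
  tmb$hypermutated <- call_hypermutation(tmb$tmb, tmb$platform)

  # --- stage 2: signatures -------------------------------------------------
  icc_wes <- cl$sample_id[cl$subtype == "ICC" & cl$platform == "WES"]
  hyper_ids <- tmb$sample_id[tmb$hypermutated]
  catalog <- suppressWarnings(
    build_context_matrix(cohort$variants, sample_ids = icc_wes,
                         drop_samples = hyper_ids))
  catalog <- catalog[, colSums(catalog) >= opts$min_catalog_mutations,
                     drop = FALSE]
  signatures <- NULL; attribution <- NULL; rank_diag <- NULL
  if (ncol(catalog) >= 2 && sum(catalog) > 0) {
    k <- opts$k
    if (identical(k, "auto")) {
      sel <- select_rank(catalog, opts$k_range, seed = seed + 101L)
      k <- sel$k; rank_diag <- sel$diagnostics
    }
    signatures <- nmf_decompose(catalog, k = k, seed = seed + 102L,
                                n_init = opts$n_init)
    signatures$matches <- cosine_match(signatures$profiles, opts$reference)
    # attribution runs against the matched *reference* profiles: de-novo
    # extraction discovers which processes are active, but fitted profiles
    # trade overlapping mass between factors, which would bias a
    # per-sample presence test; the reference catalog is the stable basis
    ref_names <- unique(signatures$matches$reference)
    if (opts$target_reference %in% ref_names && length(ref_names) >= 2) {
      ref_set <- list(profiles = opts$reference[, ref_names, drop = FALSE],
                      exposures = NULL, k = length(ref_names),
                      reconstruction_error = NA_real_, matches = NULL)
      class(ref_set) <- "signature_set"
      attribution <- attribute_signature(
        catalog, ref_set, which(ref_names == opts$target_reference),
        n_null = opts$n_null, seed = seed + 103L, fdr = opts$fdr)
    }
  }

  # --- stage 3: pairwise association --------------------------------------
  ind <- mutation_indicator_matrix(cohort$variants, sample_ids = cl$sample_id)
  freq_genes <- rownames(ind)[rowMeans(ind) >= opts$min_gene_freq &
                                !startsWith(rownames(ind), "BG")]
  pairwise <- if (length(freq_genes) >= 2)
    pairwise_gene_tests(ind[freq_genes, , drop = FALSE], fdr = opts$fdr)
  else NULL

  # --- stage 4: DDR --------------------------------------------------------
  ddr_map <- load_ddr_map()
  ddr <- classify_ddr(cohort$variants, ddr_map, sample_ids = cl$sample_id)
  ddr_summary <- summarize_ddr(ddr)

  # --- stage 5: actionability ----------------------------------------------
  kb <- load_knowledge_base()
  v_by <- split(cohort$variants, factor(cohort$variants$sample_id,
                                        levels = cl$sample_id))
  c_by <- split(cohort$copy_number, factor(cohort$copy_number$sample_id,
                                           levels = cl$sample_id))
  f_by <- split(cohort$fusions, factor(cohort$fusions$sample_id,
                                       levels = cl$sample_id))
  calls_by_patient <- lapply(seq_len(nrow(cl)), function(i)
    annotate_patient(v_by[[i]], c_by[[i]], f_by[[i]], cl[i, , drop = FALSE], kb))
  names(calls_by_patient) <- cl$sample_id
  pat_summary <- summarize_pat_prevalence(calls_by_patient, cl)

  # --- stage 6: outcomes ---------------------------------------------------
  outcomes <- NULL
  if (nrow(cohort$outcomes) > 0) {
    orr <- classify_response_and_orr(cohort$outcomes)
    ben <- pfs_ratio_benefit(cohort$outcomes)
    km <- km_estimate(cohort$outcomes$pfs2_months,
                      if ("pfs2_event" %in% names(cohort$outcomes))
                        cohort$outcomes$pfs2_event else TRUE)
    outcomes <- list(orr = orr, benefit = ben, km = km)
  }

  # --- headline summary ----------------------------------------------------
  n <- nrow(cl)
  n_panel <- sum(cl$platform == "TPS")
  germ <- sum(cl$germline_pathogenic_genes != "" &
                !is.na(cl$germline_pathogenic_genes))
  panel_ids <- cl$sample_id[cl$platform == "TPS"]
  fgfr <- length(intersect(panel_ids, cohort$fusions$sample_id[
    cohort$fusions$gene_5p %in% c("FGFR2", "FGFR3") |
      cohort$fusions$gene_3p %in% c("FGFR2", "FGFR3")]))
  counts <- list(
    hypermutated = c(sum(tmb$hypermutated), n),
    germline_pathogenic = c(germ, n),
    ddr_mutant = c(ddr_summary$n_mutant, n),
    msi_high = c(sum(cl$msi_high), n),
    ge1_pat = c(pat_summary$n_ge1_pat, n)
  )
  if (n_panel > 0) counts$fgfr_fusion <- c(fgfr, n_panel)
  if (!is.null(attribution))
    counts$aa_signature_positive <- c(sum(attribution$positive),
                                      nrow(attribution))
  if (!is.null(outcomes)) {
    counts$orr <- c(outcomes$orr$n_responders, outcomes$orr$n_treated)
    if (outcomes$benefit$n_ratio_defined > 0)
      counts$pfs_benefit <- c(outcomes$benefit$n_benefit,
                              outcomes$benefit$n_ratio_defined)
  }
  summary_tab <- summarize_counts(counts)
  extra <- data.frame(name = "non_tp53_ddr",
                      numerator = ddr_summary$n_non_tp53_pool,
                      denominator = NA_real_, percent = NA_real_,
                      display = as.character(ddr_summary$n_non_tp53_pool),
                      stringsAsFactors = FALSE)
  summary_tab <- rbind(summary_tab, extra)

  res <- list(tmb = tmb, signatures = signatures, rank_diagnostics = rank_diag,
              attribution = attribution, pairwise = pairwise, ddr = ddr,
              ddr_summary = ddr_summary, calls_by_patient = calls_by_patient,
              pat_summary = pat_summary, outcomes = outcomes,
              summary = summary_tab, seed = seed)
  class(res) <- "cohort_summary"
  if (!is.null(out_dir)) .write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    if (is.na(r$denominator)) {
      cat(sprintf("  %-24s %s\n", r$name, r$display))
    } else {
      cat(sprintf("  %-24s %s (%d/%d)\n", r$name, r$display,
                  as.integer(r$numerator), as.integer(r$denominator)))
    }
  }
  invisible(x)
}

.write_pipeline_artifacts <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(res$tmb, "tmb.tsv")
  if (!is.null(res$signatures)) {
    wr(data.frame(channel = rownames(res$signatures$profiles),
                  res$signatures$profiles, check.names = FALSE),
       "signature_profiles.tsv")
    wr(data.frame(signature = rownames(res$signatures$exposures),
                  res$signatures$exposures, check.names = FALSE),
       "signature_exposures.tsv")
    wr(res$signatures$matches, "signature_matches.tsv")
  }
  if (!is.null(res$attribution)) wr(res$attribution, "attribution.tsv")
  if (!is.null(res$pairwise)) wr(res$pairwise, "pairwise_tests.tsv")
  wr(res$ddr, "ddr_status.tsv")
  wr(res$summary, "summary.tsv")
  jsonlite::write_json(
    list(seed = res$seed,
         summary = res$summary,
         ddr = res$ddr_summary[c("n", "n_mutant", "n_tp53_attributed",
                                 "n_non_tp53_pool", "mutant_percent")],
         pat = res$pat_summary[c("n_patients", "n_ge1_pat", "n_ge2_pat",
                                 "ge1_percent")]),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(NULL)
}
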