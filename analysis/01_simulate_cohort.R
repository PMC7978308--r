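#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
# Generates the study-like synthetic cohort (803 patients; subtype and
# platform proportions, log-normal TMB with a hypermutated tail, planted
# driver frequencies with pairwise co-occurrence/exclusivity, planted
# signature mixtures, actionable alterations, MSI-H/germline flags and
# therapy outcomes) and writes it, with its planted truth, under results/.

suppressMessages(library(btcprof))

seed <- 20260925L
cfg <- btc_cohort_config(n_samples = 803L, seed = seed)
g <- generate_cohort(cfg)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
write_cohort(g$cohort, "results/cohort")

truth <- g$truth$samples
utils::write.table(truth, "results/truth_samples.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       n_samples = nrow(truth),
       planted = list(
         hypermutated_frac = cfg$hypermutated_frac,
         aa_positive_frac = cfg$aa_positive_frac,
         msi_frac = cfg$msi_frac,
         gene_freqs = as.list(cfg$gene_freqs),
         pat_freqs = setNames(as.list(cfg$pat_spec$freq), cfg$pat_spec$target)),
       realized = list(
         n_hypermutated = sum(truth$hypermutated),
         n_aa_positive = sum(truth$aa_positive),
         n_msi = sum(truth$msi_high),
         n_pat_carrier = sum(truth$pat_carrier),
         n_treated = sum(truth$treated))),
  "results/truth_summary.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("cohort: %d samples, %d variants, %d CNAs, %d fusions, %d outcomes\n",
            nrow(g$cohort$clinical), nrow(g$cohort$variants),
            nrow(g$cohort$copy_number), nrow(g$cohort$fusions),
            nrow(g$cohort$outcomes)))
cat(sprintf("planted: %d hypermutated, %d MSI-H, %d PAT carriers (%d treated)\n",
            sum(truth$hypermutated), sum(truth$msi_high),
            sum(truth$pat_carrier), sum(truth$treated)))
cat("written to results/cohort/\n")
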