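#!/usr/bin/env Rscript
# Stage 5 -- actionability and therapy outcomes.
# Annotates every patient's alterations against the PAT knowledge base,
# applies the MTB prioritization rules, summarizes PAT prevalence, and
# evaluates the treated subset: RECIST objective response rate,
# Kaplan-Meier PFS and the PFS2/PFS1 >= 1.3 benefit rule.

suppressMessages(library(btcprof))

co <- read_cohort("results/cohort")
cl <- co$clinical
kb <- load_knowledge_base()

v_by <- split(co$variants, factor(co$variants$sample_id, levels = cl$sample_id))
c_by <- split(co$copy_number, factor(co$copy_number$sample_id, levels = cl$sample_id))
f_by <- split(co$fusions, factor(co$fusions$sample_id, levels = cl$sample_id))
calls <- lapply(seq_len(nrow(cl)), function(i)
  annotate_patient(v_by[[i]], c_by[[i]], f_by[[i]], cl[i, , drop = FALSE], kb))
names(calls) <- cl$sample_id

tops <- lapply(seq_len(nrow(cl)), function(i)
  prioritize(calls[[i]], cl[i, , drop = FALSE])$top)
top_tab <- do.call(rbind, tops[!vapply(tops, is.null, TRUE)])
utils::write.table(top_tab, "results/mtb_top_picks.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

sm <- summarize_pat_prevalence(calls, cl)
cat(sprintf("PAT carriers: %d/%d (%.1f%%); %d patients with two or more PATs\n",
            sm$n_ge1_pat, sm$n_patients, sm$ge1_percent, sm$n_ge2_pat))
cat("per-subtype PAT prevalence:\n"); print(sm$per_subtype)
cat("most frequent targets:\n"); print(utils::head(sm$per_target, 8))
utils::write.table(sm$per_target, "results/pat_per_target.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

ou <- co$outcomes
if (nrow(ou)) {
  orr <- classify_response_and_orr(ou)
  cat(sprintf("ORR among treated patients: %d/%d (%.1f%%)\n",
              orr$n_responders, orr$n_treated, orr$orr_percent))
  km <- km_estimate(ou$pfs2_months, ou$pfs2_event)
  cat(sprintf("median PFS on matched therapy: %.1f months (95%% CI %.1f-%.1f)\n",
              km$median, km$median_ci["lower"], km$median_ci["upper"]))
  ben <- pfs_ratio_benefit(ou)
  cat(sprintf("PFS2/PFS1 >= 1.3: %d/%d (%.1f%%); %d PFS1 unmeasurable, %d censored PFS2 excluded\n",
              ben$n_benefit, ben$n_ratio_defined, ben$benefit_percent,
              ben$n_pfs1_missing, ben$n_pfs2_censored_excluded))
  utils::write.table(ben$outcomes, "results/therapy_outcomes.tsv", sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
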