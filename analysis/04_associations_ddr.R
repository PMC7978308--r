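#!/usr/bin/env Rscript
# Stage 4 -- driver-gene associations and DDR classification.
# Tests every frequent-gene pair for co-occurrence / mutual exclusivity
# (two-sided Fisher, BH FDR 0.05), classifies each sample's DDR status
# against the 47-gene pathway map, and compares TMB between DDR-mutant
# and wild-type patients and between AA-positive and AA-negative ICCs.

suppressMessages(library(btcprof))

co <- read_cohort("results/cohort")
cl <- co$clinical
tmb <- utils::read.delim("results/tmb.tsv")

ind <- mutation_indicator_matrix(co$variants, sample_ids = cl$sample_id)
genes <- rownames(ind)[rowMeans(ind) >= 0.05 & !startsWith(rownames(ind), "BG")]
pw <- pairwise_gene_tests(ind[genes, , drop = FALSE])
utils::write.table(pw, "results/pairwise_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
hits <- pw[pw$direction != "none", ]
cat(sprintf("pairwise tests: %d pairs over %d genes, %d significant at FDR 0.05\n",
            nrow(pw), length(genes), nrow(hits)))
print(hits[, c("gene_a", "gene_b", "odds_ratio", "q_value", "direction")])

ddr <- classify_ddr(co$variants, sample_ids = cl$sample_id)
sm <- summarize_ddr(ddr)
utils::write.table(ddr, "results/ddr_status.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("DDR mutants: %d/%d (%.1f%%); %d TP53-attributed, %d non-TP53\n",
            sm$n_mutant, sm$n, sm$mutant_percent, sm$n_tp53_attributed,
            sm$n_non_tp53_pool))

ddr_mut <- ddr$status != "wild_type"
tt <- group_tmb_test(tmb$tmb[match(ddr$sample_id, tmb$sample_id)],
                     ifelse(ddr_mut, "DDR_mutant", "DDR_wild_type"))
cat(sprintf("TMB, DDR-mutant vs wild-type: means %.2f vs %.2f Mut/Mb, Welch p = %.3g\n",
            tt$group_means[["DDR_mutant"]], tt$group_means[["DDR_wild_type"]],
            tt$p_value))

att <- utils::read.delim("results/aa_attribution.tsv")
aa_tmb <- tmb$tmb[match(att$sample_id, tmb$sample_id)]
if (sum(att$positive) >= 2 && sum(!att$positive) >= 2) {
  t2 <- group_tmb_test(aa_tmb, ifelse(att$positive, "AA", "non_AA"))
  cat(sprintf("TMB, AA vs non-AA ICC: means %.2f vs %.2f Mut/Mb, Welch p = %.3g\n",
              t2$group_means[["AA"]], t2$group_means[["non_AA"]], t2$p_value))
}
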