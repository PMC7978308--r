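# shared fixture builders; everything is generated in code

# minimal hand-built cohort: two samples, a handful of alterations
tiny_cohort <- function() {
  clinical <- data.frame(
    sample_id = c("P1", "P2"),
    subtype = c("ICC", "GBC"),
    stage = c("II", "III_IV"),
    hepatitis = c("negative", "positive"),
    platform = c("WES", "TPS"),
    msi_high = c(FALSE, TRUE),
    egfr_ihc_2plus = c(TRUE, FALSE),
    germline_pathogenic_genes = c("BRCA2", ""),
    stringsAsFactors = FALSE)
  variants <- data.frame(
    sample_id = c("P1", "P1", "P2"),
    gene = c("TP53", "KRAS", "ARID1A"),
    chrom = c("17", "12", "1"),
    pos = c(7578406, 25398284, 27023003),
    ref = c("C", "C", "G"),
    alt = c("T", "A", "A"),
    variant_class = c("missense", "missense", "nonsense"),
    vaf = c(0.42, 0.31, NA),
    context_channel = c(39, 6, 60),
    stringsAsFactors = FALSE)
  cnas <- data.frame(sample_id = "P2", gene = "ERBB2",
                     cna_type = "amplification", cytoband = NA_character_,
                     stringsAsFactors = FALSE)
  fusions <- data.frame(sample_id = "P2", gene_5p = "FGFR2",
                        gene_3p = "BICC1", stringsAsFactors = FALSE)
  outcomes <- data.frame(patient_id = "P2", matched_target = "MSI-H",
                         best_response = "PR", pfs2_months = 6.5,
                         pfs2_event = TRUE, pfs1_months = 5.0,
                         stringsAsFactors = FALSE)
  new_cohort(variants, cnas, fusions, clinical, outcomes)
}

# planted three-signature catalog used across the signature tests
planted_catalog <- function(n_samples = 150, seed = 4107,
                            alpha = c(1, 1, 1), base_mut = 50,
                            extra_mut = 150) {
  set.seed(seed)
  prof <- synthetic_reference_signatures()[, c("SBS1_like", "SBS22_like",
                                               "SBS40_like")]
  expo <- t(vapply(seq_len(n_samples), function(i) {
    g <- stats::rgamma(3, shape = alpha)
    g / sum(g)
  }, numeric(3)))
  V <- vapply(seq_len(n_samples), function(i) {
    nm <- base_mut + stats::rpois(1, extra_mut)
    tabulate(sample_mutation_channels(prof, expo[i, ], nm) + 1, nbins = 96)
  }, numeric(96))
  rownames(V) <- sbs_channels()
  colnames(V) <- sprintf("T%03d", seq_len(n_samples))
  list(catalog = V, profiles = prof, exposures = expo)
}

# independent Fisher oracle: full hypergeometric enumeration with fixed
# margins, two-sided by the "probability mass <= observed" rule
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# signature_set wrapper around known profiles, for attribution tests
as_signature_set <- function(profiles) {
  out <- list(profiles = profiles, exposures = NULL, k = ncol(profiles),
              reconstruction_error = NA_real_, matches = NULL)
  class(out) <- "signature_set"
  out
}
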