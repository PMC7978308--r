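#' @title Synthetic cohort generator with planted ground truth
#' @description Generates cohorts carrying the statistical structure the
#'   downstream analyses assume — log-normal TMB with a hypermutated tail,
#'   96-channel mutation contexts drawn from planted signature mixtures
#'   (including an SBS22-like A:T>T:A-dominant process in a subset of
#'   ICCs), planted driver-gene frequencies with pairwise
#'   co-occurrence/exclusivity, planted actionable alterations, MSI-H and
#'   germline flags, and exponential progression-free survival with
#'   censoring. Every generated cohort is paired with its planted truth so
#'   estimator-recovery tests need no external data.
#' @name synthetic_cohort
NULL

#' Default BTC cohort configuration
#'
#' Encodes the study conditions the generator emulates: subtype and
#' platform proportions, a log-normal TMB with median 1.23 Mut/Mb and IQR
#' 0.7-2.34 (WES), a 4.1% hypermutated fraction above the platform
#' thresholds, driver-gene frequencies led by TP53 (53%) and KRAS (26%)
#' with planted pairwise co-occurrence (TP53:CDKN2A, KRAS:SMAD4) and
#' exclusivity (TP53:IDH1, KRAS:LRP1B), a three-signature mixture
#' (CpG C>T clock-like, SBS22-like, flat) with 35.8% of ICCs
#' AA-signature-positive, actionable-alteration frequencies, 1.2% MSI-H,
#' germline pathogenic-gene frequencies, and therapy outcomes with a
#' 5-month median PFS2 and 26.1% responder fraction.
#'
#' @param n_samples Cohort size (default 803).
#' @param seed Integer seed (mandatory for generation).
#' @return A config list accepted by [generate_cohort()].
#' @export
btc_cohort_config <- function(n_samples = 803L, seed = 1L) {
  ref <- synthetic_reference_signatures()
  list(
    n_samples = as.integer(n_samples),
    seed = as.integer(seed),
    subtype_props = c(ICC = 475, ECC = 164, GBC = 164) / 803,
    platform_props = c(WES = 160, TPS = 643) / 803,
    stage_props = c(I = 0.15, II = 0.25, III_IV = 0.50, unknown = 0.10),
    hepatitis_props = c(positive = 0.30, negative = 0.60, unknown = 0.10),
    region_mb = c(WES = 38, TPS = 1.5),
    tmb_log_mean = log(1.23),
    tmb_log_sd = (log(2.34) - log(0.7)) / (2 * stats::qnorm(0.75)),
    hypermutated_frac = 33 / 803,
    # driver frequencies; genes the actionability KB recognizes by mutation
    # class are planted only through pat_spec so every planted prevalence
    # has a single source
    gene_freqs = c(TP53 = 0.53, KRAS = 0.26, ARID1A = 0.18, LRP1B = 0.16,
                   CDKN2A = 0.14, SMAD4 = 0.10, TERT = 0.09, MUC4 = 0.06,
                   EPHA2 = 0.05, KMT2C = 0.09, ATM = 0.07, PRKDC = 0.05,
                   ATR = 0.04, POLE = 0.04, MSH6 = 0.03, FANCA = 0.02,
                   CHEK2 = 0.02, MLH1 = 0.02, MSH2 = 0.02),
    pair_effects = list(
      list(genes = c("TP53", "CDKN2A"), log_odds = 1.0),
      list(genes = c("KRAS", "SMAD4"), log_odds = 1.0),
      list(genes = c("TP53", "ARID1A"), log_odds = -2.0),
      list(genes = c("KRAS", "LRP1B"), log_odds = -1.5)
    ),
    signature_profiles = ref[, c("SBS1_like", "SBS22_like", "SBS40_like")],
    exposure_alpha_aa = c(2, 6, 2),
    exposure_alpha_background = c(4, 0, 4),
    aa_positive_frac = 53 / 148,
    # planted actionable alterations; `pat` marks tiers at or above the
    # PAT threshold (the CDKN2A deletion is a deliberate off-PAT entry)
    pat_spec = data.frame(
      target = c("MET", "ERBB2", "CDK4", "CDKN2A", "FGFR2", "FGFR3",
                 "NTRK1", "IDH1", "BRAF", "EGFR", "BRCA2", "BRCA1",
                 "PIK3CA"),
      alteration_class = c("amplification", "amplification", "amplification",
                           "deletion", "fusion", "fusion", "fusion",
                           "activating_mutation", "activating_mutation",
                           "activating_mutation", "truncating_mutation",
                           "truncating_mutation", "activating_mutation"),
      freq = c(0.050, 0.050, 0.020, 0.057, 0.030, 0.010, 0.005, 0.07,
               0.015, 0.010, 0.025, 0.015, 0.020),
      pat = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
              TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE),
    fusion_partners = c(FGFR2 = "BICC1", FGFR3 = "TACC3", NTRK1 = "TPM3"),
    msi_frac = 10 / 803,
    egfr_ihc_frac = 0.30,
    germline_spec = c(PRSS1 = 24, SPINK1 = 8, BRCA2 = 10, MUTYH = 9,
                      BRCA1 = 8, ATM = 6, PALB2 = 5, MSH2 = 4, RAD51C = 4,
                      CHEK2 = 4, FANCA = 4, NBN = 4, POLE = 3, MLH1 = 3,
                      XPC = 4) / 803,
    outcome_spec = list(median_pfs2_months = 5.0, median_pfs1_months = 2.5,
                        responder_frac = 12 / 46, pfs1_missing_frac = 9 / 46,
                        censor_frac = 0.2, treated_frac = 46 / 204)
  )
}

#' Validate a cohort configuration
#'
#' @param config Config list (see [btc_cohort_config()]).
#' @return Invisibly `TRUE`; stops on structural errors, warns on
#'   implausible-but-feasible settings.
#' @export
validate_cohort_config <- function(config) {
  if (is.null(config$seed)) stop("config seed is mandatory", call. = FALSE)
  fracs <- c(config$hypermutated_frac, config$aa_positive_frac,
             config$msi_frac, config$gene_freqs, config$germline_spec,
             config$pat_spec$freq,
             config$outcome_spec$responder_frac,
             config$outcome_spec$pfs1_missing_frac)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions must lie in [0,1]", call. = FALSE)
  for (p in list(config$subtype_props, config$platform_props,
                 config$stage_props, config$hepatitis_props)) {
    if (abs(sum(p) - 1) > 1e-9)
      stop("probability vectors must sum to 1", call. = FALSE)
  }
  if (any(config$signature_profiles < 0))
    stop("signature profiles must be non-negative", call. = FALSE)
  if (any(abs(colSums(config$signature_profiles) - 1) > 1e-9))
    stop("each signature profile must sum to 1", call. = FALSE)
  if (config$hypermutated_frac > 0.5)
    warning("hypermutated_frac > 0.5 is far outside the regime the burden model emulates",
            call. = FALSE)
  invisible(TRUE)
}

#' Draw mutation context channels from a signature mixture
#'
#' Channels are drawn i.i.d. from the mixture
#' `sum_j exposure[j] * profile[, j]`.
#'
#' @param signature_profiles 96 x k column-stochastic matrix.
#' @param exposure Length-k non-negative weights summing to 1.
#' @param n_mut Number of draws (>= 0).
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return Integer vector of 0-based channel codes, length `n_mut`.
#' @export
sample_mutation_channels <- function(signature_profiles, exposure, n_mut,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(signature_profiles < 0))
    stop("signature profiles must be non-negative", call. = FALSE)
  if (abs(sum(exposure) - 1) > 1e-9 || any(exposure < 0))
    stop("exposure must be a probability vector", call. = FALSE)
  if (n_mut < 0) stop("n_mut must be >= 0", call. = FALSE)
  if (n_mut == 0) return(integer(0))
  p <- as.vector(signature_profiles %*% exposure)
  sample(0:95, size = n_mut, replace = TRUE, prob = p)
}

# Ising-style pairwise model for gene statuses: independent Bernoulli base
# measures (gene_freqs) tilted by exp(log_odds * x_a * x_b) for each pair.
# Connected components of the pair graph are sampled exactly by enumerating
# their 2^m states (components stay tiny). Tilting shifts the marginals;
# the exact tilted marginals are returned for recovery tests.
.sample_gene_matrix <- function(n, gene_freqs, pair_effects) {
  genes <- names(gene_freqs)
  m <- matrix(FALSE, nrow = length(genes), ncol = n,
              dimnames = list(genes, NULL))
  marginals <- gene_freqs
  comp <- stats::setNames(seq_along(genes), genes)  # union-find by relabel
  for (pe in pair_effects) {
    ga <- pe$genes[1]; gb <- pe$genes[2]
    if (!all(c(ga, gb) %in% genes))
      stop(sprintf("pair effect names unknown gene: %s:%s", ga, gb), call. = FALSE)
    comp[comp == comp[[gb]]] <- comp[[ga]]
  }
  for (cid in unique(comp)) {
    members <- genes[comp == cid]
    k <- length(members)
    if (k == 1) {
      m[members, ] <- stats::runif(n) < gene_freqs[[members]]
      next
    }
    if (k > 12) stop("pair-effect component too large to enumerate", call. = FALSE)
    states <- as.matrix(expand.grid(rep(list(0:1), k)))
    colnames(states) <- members
    p <- gene_freqs[members]
    logw <- states %*% log(p) + (1 - states) %*% log(1 - p)
    for (pe in pair_effects) {
      if (all(pe$genes %in% members))
        logw <- logw + pe$log_odds * states[, pe$genes[1]] * states[, pe$genes[2]]
    }
    w <- exp(logw - max(logw)); w <- w / sum(w)
    marginals[members] <- as.vector(crossprod(states, w))
    drawn <- states[sample.int(nrow(states), n, replace = TRUE, prob = w), ,
                    drop = FALSE]
    m[members, ] <- t(drawn) == 1
  }
  attr(m, "marginals") <- marginals
  m
}

#' Simulate therapy outcomes
#'
#' PFS2 is exponential with the configured median (rate log(2)/median),
#' independently censored with probability `censor_frac`; PFS1 is
#' exponential with its own median and present with probability
#' `1 - pfs1_missing_frac`; the best RECIST response is a responder
#' (CR/PR) with probability `responder_frac`.
#'
#' @param patient_ids Character vector of treated patients.
#' @param outcome_spec List with `median_pfs2_months`,
#'   `median_pfs1_months`, `responder_frac`, `pfs1_missing_frac`,
#'   `censor_frac`.
#' @param seed Optional seed.
#' @param matched_targets Optional character vector aligned with
#'   `patient_ids`.
#' @return Outcomes data frame in package schema.
#' @export
simulate_outcomes <- function(patient_ids, outcome_spec, seed = NULL,
                              matched_targets = NULL) {
  if (!is.null(seed)) set.seed(seed)
  os <- outcome_spec
  if (os$responder_frac < 0 || os$responder_frac > 1 ||
      os$pfs1_missing_frac < 0 || os$pfs1_missing_frac > 1)
    stop("responder_frac and pfs1_missing_frac must lie in [0,1]", call. = FALSE)
  n <- length(patient_ids)
  if (n == 0) return(empty_cohort_table("outcomes"))
  responder <- stats::runif(n) < os$responder_frac
  best <- ifelse(responder,
                 ifelse(stats::runif(n) < 0.25, "CR", "PR"),
                 ifelse(stats::runif(n) < 0.5, "SD", "PD"))
  rate2 <- log(2) / os$median_pfs2_months
  t_event <- stats::rexp(n, rate = rate2)
  cf <- os$censor_frac %||% 0
  if (cf > 0) {
    # independent exponential censoring with rate chosen so the expected
    # censored fraction is censor_frac: P(C < T) = rc / (rc + rate2)
    rc <- rate2 * cf / (1 - cf)
    t_cens <- stats::rexp(n, rate = rc)
    event <- t_event <= t_cens
    pfs2 <- pmin(t_event, t_cens)
  } else {
    event <- rep(TRUE, n)
    pfs2 <- t_event
  }
  pfs1 <- stats::rexp(n, rate = log(2) / os$median_pfs1_months)
  pfs1[stats::runif(n) < os$pfs1_missing_frac] <- NA_real_
  data.frame(patient_id = patient_ids,
             matched_target = if (is.null(matched_targets))
               rep(NA_character_, n) else matched_targets,
             best_response = best,
             pfs2_months = pfs2, pfs2_event = event, pfs1_months = pfs1,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with planted truth
#'
#' Deterministic given `config$seed`. Per sample the generator draws
#' subtype/platform/stage, a log-normal TMB (hypermutated samples from a
#' shifted tail at or above the platform threshold, background samples
#' rejected below it), plants driver-gene statuses (pairwise effects
#' preserve the marginal frequencies), emits context-carrying SBS variants
#' from the sample's signature mixture so that the total mutation count
#' matches TMB x region size (stochastic rounding), plants actionable
#' copy-number events, fusions and mutations, MSI-H, germline flags, and
#' simulates therapy outcomes for a treated subset of PAT carriers.
#'
#' @param config Config list (see [btc_cohort_config()]).
#' @return List with `cohort` (a `btc_cohort`) and `truth` (per-sample
#'   planted values: TMB, hypermutation, signature exposures, AA
#'   positivity, gene statuses, PAT carriage, treated flag, plus the
#'   config echo).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  if (n == 0) {
    return(list(cohort = new_cohort(),
                truth = list(samples = data.frame(), exposures = NULL,
                             gene_status = NULL, config = config)))
  }
  ids <- sprintf("S%04d", seq_len(n))
  subtype <- sample(names(config$subtype_props), n, replace = TRUE,
                    prob = config$subtype_props)
  platform <- sample(names(config$platform_props), n, replace = TRUE,
                     prob = config$platform_props)
  stage <- sample(names(config$stage_props), n, replace = TRUE,
                  prob = config$stage_props)
  hepatitis <- sample(names(config$hepatitis_props), n, replace = TRUE,
                      prob = config$hepatitis_props)
  msi <- stats::runif(n) < config$msi_frac
  egfr_ihc <- stats::runif(n) < config$egfr_ihc_frac
  germ <- vapply(seq_len(n), function(i) {
    g <- names(config$germline_spec)[stats::runif(length(config$germline_spec)) <
                                       config$germline_spec]
    paste(g, collapse = ",")
  }, character(1))

  # TMB: hypermutated tail at/above the platform threshold; background
  # rejected below it so the planted flag and the called flag coincide
  hyper <- stats::runif(n) < config$hypermutated_frac
  thr <- .HYPERMUTATION_THRESHOLDS[platform]
  tmb <- exp(stats::rnorm(n, config$tmb_log_mean, config$tmb_log_sd))
  for (i in which(!hyper & tmb >= thr))
    while (tmb[i] >= thr[i])
      tmb[i] <- exp(stats::rnorm(1, config$tmb_log_mean, config$tmb_log_sd))
  tmb[hyper] <- thr[hyper] * exp(abs(stats::rnorm(sum(hyper), 0, 0.5)))

  mb <- config$region_mb[platform]
  n_target <- floor(tmb * mb) +
    (stats::runif(n) < (tmb * mb - floor(tmb * mb)))
  # keep counted TMB on the planted side of the threshold: hypermutated
  # samples get at least ceiling(tmb*mb) mutations, background samples are
  # capped one mutation below the platform cutoff
  n_target[hyper] <- pmax(n_target[hyper], ceiling((tmb * mb)[hyper]))
  cap <- ceiling(thr * mb) - 1
  n_target[!hyper] <- pmin(n_target[!hyper], cap[!hyper])

  # planted signature exposures; AA positivity only among ICCs
  k <- ncol(config$signature_profiles)
  aa_idx <- which(colnames(config$signature_profiles) == "SBS22_like")
  if (length(aa_idx) == 0) aa_idx <- 2L
  aa_pos <- subtype == "ICC" & stats::runif(n) < config$aa_positive_frac
  expo <- matrix(0, nrow = k, ncol = n)
  for (i in seq_len(n)) {
    alpha <- if (aa_pos[i]) config$exposure_alpha_aa else
      config$exposure_alpha_background
    g <- ifelse(alpha > 0, stats::rgamma(k, shape = alpha), 0)
    expo[, i] <- g / sum(g)
  }
  rownames(expo) <- colnames(config$signature_profiles)
  colnames(expo) <- ids

  gene_status <- .sample_gene_matrix(n, config$gene_freqs, config$pair_effects)
  colnames(gene_status) <- ids

  # planted actionable alterations
  ps <- config$pat_spec
  pat_hit <- matrix(stats::runif(nrow(ps) * n) < rep(ps$freq, n),
                    nrow = nrow(ps), ncol = n, dimnames = list(ps$target, ids))
  # fusions are only assayed on the panel platform, so they are only
  # planted there (the per-target frequency is a panel prevalence)
  pat_hit[ps$alteration_class == "fusion", platform == "WES"] <- FALSE

  var_rows <- vector("list", n)
  cna_rows <- list(); fus_rows <- list()
  driver_class_pool <- c("missense", "nonsense", "frameshift_indel")
  for (i in seq_len(n)) {
    rows <- list()
    pos_next <- 1L
    add_snv <- function(gene, channel, vclass) {
      ra <- channel_ref_alt(channel)
      r <- data.frame(sample_id = ids[i], gene = gene, chrom = "1",
                      pos = pos_next * 100, ref = ra$ref, alt = ra$alt,
                      variant_class = vclass, vaf = stats::runif(1, 0.05, 0.6),
                      context_channel = channel, stringsAsFactors = FALSE)
      pos_next <<- pos_next + 1L
      r
    }
    genes_i <- rownames(gene_status)[gene_status[, i]]
    for (g in genes_i) {
      if (g == "TERT") {
        ch <- sample_mutation_channels(config$signature_profiles, expo[, i], 1)
        rows[[length(rows) + 1]] <- add_snv(g, ch, "TERT_promoter")
      } else {
        cls <- sample(driver_class_pool, 1, prob = c(0.6, 0.2, 0.2))
        if (cls == "frameshift_indel") {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = ids[i], gene = g, chrom = "1", pos = pos_next * 100,
            ref = "A", alt = "AT", variant_class = cls,
            vaf = stats::runif(1, 0.05, 0.6), context_channel = NA_real_,
            stringsAsFactors = FALSE)
          pos_next <- pos_next + 1L
        } else {
          ch <- sample_mutation_channels(config$signature_profiles, expo[, i], 1)
          rows[[length(rows) + 1]] <- add_snv(g, ch, cls)
        }
      }
    }
    for (j in which(pat_hit[, i])) {
      tgt <- ps$target[j]; acl <- ps$alteration_class[j]
      if (acl %in% c("amplification", "deletion")) {
        cna_rows[[length(cna_rows) + 1]] <- data.frame(
          sample_id = ids[i], gene = tgt, cna_type = acl,
          cytoband = if (tgt == "MET") "7q31.2" else NA_character_,
          stringsAsFactors = FALSE)
      } else if (acl == "fusion") {
        cna_partner <- config$fusion_partners[[tgt]] %||% "UNKNOWN"
        fus_rows[[length(fus_rows) + 1]] <- data.frame(
          sample_id = ids[i], gene_5p = tgt, gene_3p = cna_partner,
          stringsAsFactors = FALSE)
      } else if (acl == "activating_mutation") {
        ch <- sample_mutation_channels(config$signature_profiles, expo[, i], 1)
        rows[[length(rows) + 1]] <- add_snv(tgt, ch, "missense")
      } else {  # truncating_mutation
        if (stats::runif(1) < 0.5) {
          ch <- sample_mutation_channels(config$signature_profiles, expo[, i], 1)
          rows[[length(rows) + 1]] <- add_snv(tgt, ch, "nonsense")
        } else {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = ids[i], gene = tgt, chrom = "1", pos = pos_next * 100,
            ref = "A", alt = "AT", variant_class = "frameshift_indel",
            vaf = stats::runif(1, 0.05, 0.6), context_channel = NA_real_,
            stringsAsFactors = FALSE)
          pos_next <- pos_next + 1L
        }
      }
    }
    n_bg <- max(0, n_target[i] - length(rows))
    if (n_bg > 0) {
      chans <- sample_mutation_channels(config$signature_profiles, expo[, i], n_bg)
      ra <- channel_ref_alt(chans)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids[i], gene = sprintf("BG%03d", seq_len(n_bg) %% 500),
        chrom = "1", pos = (pos_next + seq_len(n_bg) - 1) * 100,
        ref = ra$ref, alt = ra$alt, variant_class = "missense",
        vaf = stats::runif(n_bg, 0.05, 0.6), context_channel = chans,
        stringsAsFactors = FALSE)
    }
    var_rows[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  variants <- do.call(rbind, c(var_rows, list(empty_cohort_table("variants"))))
  cnas <- do.call(rbind, c(cna_rows, list(empty_cohort_table("copy_number"))))
  fusions <- do.call(rbind, c(fus_rows, list(empty_cohort_table("fusions"))))

  pat_carrier <- colSums(pat_hit & ps$pat) > 0 | msi
  treated <- pat_carrier & stats::runif(n) < config$outcome_spec$treated_frac
  outcomes <- simulate_outcomes(ids[treated], config$outcome_spec,
                                matched_targets = vapply(which(treated),
                                  function(i) {
                                    hits <- ps$target[pat_hit[, i] & ps$pat]
                                    if (msi[i]) hits <- c("MSI-H", hits)
                                    hits[1]
                                  }, character(1)))

  clinical <- data.frame(sample_id = ids, subtype = subtype, stage = stage,
                         hepatitis = hepatitis, platform = platform,
                         msi_high = msi, egfr_ihc_2plus = egfr_ihc,
                         germline_pathogenic_genes = germ,
                         stringsAsFactors = FALSE)
  cohort <- new_cohort(variants = variants, copy_number = cnas,
                       fusions = fusions, clinical = clinical,
                       outcomes = outcomes)
  truth <- list(
    samples = data.frame(sample_id = ids, subtype = subtype,
                         platform = platform, tmb_true = unname(tmb),
                         hypermutated = unname(hyper), aa_positive = aa_pos,
                         msi_high = msi,
                         germline_pathogenic = germ != "",
                         pat_carrier = unname(pat_carrier),
                         treated = unname(treated),
                         stringsAsFactors = FALSE),
    exposures = expo,
    gene_status = gene_status,
    gene_marginals = attr(gene_status, "marginals"),
    pat_hit = pat_hit,
    config = config)
  list(cohort = cohort, truth = truth)
}
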