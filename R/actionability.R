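#' @title Rule-based precision-oncology actionability engine
#' @description Matches patient alterations (somatic variants, copy-number
#'   events, fusions, MSI-H status) against a knowledge base of potentially
#'   actionable targets (PATs) carrying OncoKB levels and ESCAT tiers,
#'   merges the two evidence scales into a single rank, and applies the
#'   molecular tumor board (MTB) prioritization rules: (I) PAT calls
#'   outrank non-PAT calls; (II) among PATs the best evidence between
#'   OncoKB and ESCAT wins; (III) an EGFR-directed call requires EGFR IHC
#'   2+/3+ overexpression.
#' @name actionability
NULL

.ONCOKB_LEVELS <- c("L1", "L2", "L3A", "L3B", "L4", "none")
.ESCAT_TIERS <- c("IA", "IB", "IC", "IIA", "IIB", "IIIA", "IIIB", "IV", "V", "none")
.ALTERATION_CLASSES <- c("activating_mutation", "truncating_mutation",
                         "amplification", "deletion", "fusion", "msi_high")

# merged cross-scale evidence rank (lower = stronger): the minimal total
# order consistent with MTB practice, in which ESCAT I-C outranks OncoKB L2
# (pembrolizumab for MSI-H beats an L2 ERBB2 amplification). Overridable in
# prioritize() via `rank_table`.
.DEFAULT_RANK <- c(IA = 1, L1 = 2, IB = 3, IC = 4, L2 = 5, IIA = 6, IIB = 7,
                   L3A = 8, L3B = 9, IIIA = 9, IIIB = 10, IV = 11, L4 = 11,
                   V = 12, none = 99)

.PAT_ONCOKB <- c("L1", "L2", "L3A")     # OncoKB tier <= level-3A
.PAT_ESCAT <- c("IA", "IB", "IC", "IIA", "IIB")  # ESCAT tier <= II-B

# variant-class groups recognized per KB alteration class
.MUT_CLASS_MATCH <- list(
  activating_mutation = c("missense", "inframe_indel"),
  truncating_mutation = c("nonsense", "frameshift_indel", "splice")
)

#' Load and validate an actionability knowledge base
#'
#' The KB is a YAML list of entries, each with `target` (gene symbol or
#' `"MSI-H"`), `alteration_class`, `oncokb_level`, `escat_tier`,
#' optional `printed_label`, `drug_hint` and a locus constraint
#' `pos_range: [min, max]` restricting matching variant positions. The
#' shipped default (`inst/extdata/pat_kb.yaml`) is a synthetic, editable
#' reconstruction naming 19 PAT genes plus MSI-H.
#'
#' @param path YAML path; defaults to the shipped KB.
#' @return Data frame of validated entries with `is_pat` precomputed, plus
#'   attributes `n_pat_genes` and `pos_ranges` (named list).
#' @export
load_knowledge_base <- function(path = system.file("extdata", "pat_kb.yaml",
                                                   package = "btcprof")) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) {
    warning("empty knowledge base", call. = FALSE)
    kb <- data.frame(target = character(0), alteration_class = character(0),
                     oncokb_level = character(0), escat_tier = character(0),
                     drug_hint = character(0), is_pat = logical(0),
                     stringsAsFactors = FALSE)
    attr(kb, "n_pat_genes") <- 0L
    attr(kb, "pos_ranges") <- list()
    return(kb)
  }
  get <- function(e, f, default = "none") if (is.null(e[[f]])) default else e[[f]]
  kb <- data.frame(
    target = vapply(raw, get, "", f = "target", default = NA_character_),
    alteration_class = vapply(raw, get, "", f = "alteration_class",
                              default = NA_character_),
    oncokb_level = vapply(raw, get, "", f = "oncokb_level"),
    escat_tier = vapply(raw, get, "", f = "escat_tier"),
    drug_hint = vapply(raw, get, "", f = "drug_hint", default = ""),
    stringsAsFactors = FALSE
  )
  if (any(is.na(kb$target)) || any(is.na(kb$alteration_class)))
    stop("every KB entry needs target and alteration_class", call. = FALSE)
  if (any(!(kb$alteration_class %in% .ALTERATION_CLASSES)))
    stop(sprintf("unknown alteration_class: %s",
                 paste(setdiff(kb$alteration_class, .ALTERATION_CLASSES),
                       collapse = ", ")), call. = FALSE)
  if (any(!(kb$oncokb_level %in% .ONCOKB_LEVELS)))
    stop("unknown oncokb_level in KB", call. = FALSE)
  if (any(!(kb$escat_tier %in% .ESCAT_TIERS)))
    stop("unknown escat_tier in KB", call. = FALSE)
  if (any(kb$oncokb_level == "none" & kb$escat_tier == "none"))
    stop("KB entry with neither an OncoKB level nor an ESCAT tier", call. = FALSE)
  key <- paste(kb$target, kb$alteration_class)
  if (anyDuplicated(key))
    stop(sprintf("duplicate KB entry: %s", key[duplicated(key)][1]), call. = FALSE)
  kb$is_pat <- kb$oncokb_level %in% .PAT_ONCOKB | kb$escat_tier %in% .PAT_ESCAT
  pr <- lapply(raw, function(e) e$pos_range)
  names(pr) <- key
  attr(kb, "pos_ranges") <- Filter(Negate(is.null), pr)
  attr(kb, "n_pat_genes") <- length(unique(kb$target[kb$is_pat & kb$target != "MSI-H"]))
  kb
}

.merged_rank <- function(oncokb, escat, rank_table = .DEFAULT_RANK) {
  pmin(unname(rank_table[oncokb]), unname(rank_table[escat]))
}

#' Annotate one patient's alterations against the knowledge base
#'
#' Emits one call per (alteration, matching KB entry). Mutation entries
#' match by gene, variant-class group and, when the entry carries a
#' `pos_range` locus constraint, by position. MSI-H produces a call iff
#' the clinical record flags MSI-high. Non-PAT (off-PAT) calls — e.g.
#' OncoKB L3B / ESCAT III entries — are emitted only with
#' `include_off_pat = TRUE`.
#'
#' @param variants,cnas,fusions This patient's alteration tables (package
#'   schema; may be empty).
#' @param clinical One-row clinical record for the patient.
#' @param kb Knowledge base from [load_knowledge_base()].
#' @param include_off_pat Emit non-PAT calls too (default FALSE).
#' @return Data frame of calls: `patient_id`, `target`,
#'   `alteration_class`, `oncokb_level`, `escat_tier`, `merged_rank`,
#'   `is_pat`, `drug_hint`.
#' @export
annotate_patient <- function(variants, cnas, fusions, clinical, kb,
                             include_off_pat = FALSE) {
  stopifnot(nrow(clinical) == 1)
  pid <- clinical$sample_id
  pos_ranges <- attr(kb, "pos_ranges")
  calls <- list()
  add <- function(i) {
    e <- kb[i, ]
    calls[[length(calls) + 1]] <<- data.frame(
      patient_id = pid, target = e$target,
      alteration_class = e$alteration_class,
      oncokb_level = e$oncokb_level, escat_tier = e$escat_tier,
      merged_rank = .merged_rank(e$oncokb_level, e$escat_tier),
      is_pat = e$is_pat, drug_hint = e$drug_hint,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(kb))) {
    e <- kb[i, ]
    matched <- switch(
      e$alteration_class,
      activating_mutation = ,
      truncating_mutation = {
        v <- variants[variants$gene == e$target &
                        variants$variant_class %in%
                        .MUT_CLASS_MATCH[[e$alteration_class]], , drop = FALSE]
        rng <- pos_ranges[[paste(e$target, e$alteration_class)]]
        if (!is.null(rng) && nrow(v))
          v <- v[v$pos >= rng[[1]] & v$pos <= rng[[2]], , drop = FALSE]
        nrow(v) > 0
      },
      amplification = ,
      deletion = any(cnas$gene == e$target & cnas$cna_type == e$alteration_class),
      fusion = any(fusions$gene_5p == e$target | fusions$gene_3p == e$target),
      msi_high = isTRUE(clinical$msi_high)
    )
    if (isTRUE(matched)) add(i)
  }
  out <- if (length(calls)) do.call(rbind, calls) else data.frame(
    patient_id = character(0), target = character(0),
    alteration_class = character(0), oncokb_level = character(0),
    escat_tier = character(0), merged_rank = numeric(0), is_pat = logical(0),
    drug_hint = character(0), stringsAsFactors = FALSE)
  if (!include_off_pat) out <- out[out$is_pat, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply MTB prioritization rules to a patient's calls
#'
#' Rule I: PAT calls outrank off-PAT calls. Rule II: within each group the
#' best merged evidence rank wins (the merged scale places ESCAT I-C above
#' OncoKB L2). Rule III: calls on EGFR are suppressed unless the patient
#' has EGFR IHC 2+/3+ overexpression (missing IHC counts as not
#' overexpressed). Ties break alphabetically by target, so the ordering is
#' total and deterministic.
#'
#' @param calls Calls from [annotate_patient()].
#' @param clinical One-row clinical record (for the EGFR IHC flag).
#' @param rank_table Named rank vector overriding the default merged
#'   evidence order.
#' @return List with `ordered` (the surviving calls, strongest first) and
#'   `top` (one-row data frame or NULL).
#' @export
prioritize <- function(calls, clinical, rank_table = NULL) {
  if (!is.null(rank_table)) {
    calls$merged_rank <- .merged_rank(calls$oncokb_level, calls$escat_tier,
                                      rank_table)
  }
  if (nrow(calls)) {
    egfr_ok <- isTRUE(clinical$egfr_ihc_2plus)
    calls <- calls[calls$target != "EGFR" | egfr_ok, , drop = FALSE]
  }
  if (nrow(calls) == 0) return(list(ordered = calls, top = NULL))
  ord <- order(!calls$is_pat, calls$merged_rank, calls$target)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  list(ordered = calls, top = calls[1, , drop = FALSE])
}

#' Cohort PAT prevalence summary
#'
#' Counts patients (not calls): patients with at least one / two or more
#' distinct PAT targets, per-subtype fractions, and per-target carrier
#' fractions, with half-up one-decimal percents.
#'
#' @param calls_by_patient Named list, one (possibly empty) call data
#'   frame per patient (names = patient ids).
#' @param clinical Clinical table covering those patients.
#' @return List with `n_patients`, `n_ge1_pat`, `n_ge2_pat`,
#'   `ge1_percent`, `per_subtype` (data frame), `per_target` (data frame).
#' @export
summarize_pat_prevalence <- function(calls_by_patient, clinical) {
  ids <- names(calls_by_patient)
  n_targets <- vapply(calls_by_patient, function(cc)
    length(unique(cc$target[cc$is_pat])), integer(1))
  n <- length(ids)
  ge1 <- sum(n_targets >= 1)
  subtype <- clinical$subtype[match(ids, clinical$sample_id)]
  per_sub <- do.call(rbind, lapply(.SUBTYPES, function(st) {
    idx <- which(subtype == st)
    data.frame(subtype = st, n = length(idx),
               n_ge1_pat = sum(n_targets[idx] >= 1),
               percent = if (length(idx))
                 percent_half_up(sum(n_targets[idx] >= 1), length(idx)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  targets <- unlist(lapply(calls_by_patient, function(cc)
    unique(cc$target[cc$is_pat])))
  per_target <- if (length(targets)) {
    tab <- sort(table(targets), decreasing = TRUE)
    data.frame(target = names(tab), n_patients = as.integer(tab),
               percent = percent_half_up(as.integer(tab), n),
               stringsAsFactors = FALSE)
  } else data.frame(target = character(0), n_patients = integer(0),
                    percent = numeric(0), stringsAsFactors = FALSE)
  list(n_patients = n,
       n_ge1_pat = ge1,
       n_ge2_pat = sum(n_targets >= 2),
       ge1_percent = if (n) percent_half_up(ge1, n) else NA_real_,
       per_subtype = per_sub,
       per_target = per_target)
}
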