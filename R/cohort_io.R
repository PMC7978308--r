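#' @title Cohort container and tabular I/O
#' @description A cohort is a list of five data frames sharing `sample_id`
#'   keys: somatic variants, copy-number alterations, fusions, clinical
#'   records and therapy outcomes. All tables are plain data frames; files
#'   are tab-separated UTF-8 with fixed headers so fixtures stay diffable.
#'   Coordinates are 1-based inclusive (MAF convention), missing values are
#'   written as empty strings and booleans as `true`/`false` literals.
#' @name cohort_io
NULL

.VARIANT_CLASSES <- c("missense", "nonsense", "frameshift_indel",
                      "inframe_indel", "splice", "synonymous",
                      "TERT_promoter", "other_noncoding")
.SUBTYPES <- c("ICC", "ECC", "GBC")
.STAGES <- c("I", "II", "III_IV", "unknown")
.HEPATITIS <- c("positive", "negative", "unknown")
.PLATFORMS <- c("WES", "TPS")
.RESPONSES <- c("CR", "PR", "SD", "PD")

.COHORT_FILES <- c(variants = "variants.tsv",
                   copy_number = "copy_number.tsv",
                   fusions = "fusions.tsv",
                   clinical = "clinical.tsv",
                   outcomes = "outcomes.tsv")

.COHORT_COLUMNS <- list(
  variants = c("sample_id", "gene", "chrom", "pos", "ref", "alt",
               "variant_class", "vaf", "context_channel"),
  copy_number = c("sample_id", "gene", "cna_type", "cytoband"),
  fusions = c("sample_id", "gene_5p", "gene_3p"),
  clinical = c("sample_id", "subtype", "stage", "hepatitis", "platform",
               "msi_high", "egfr_ihc_2plus", "germline_pathogenic_genes"),
  outcomes = c("patient_id", "matched_target", "best_response",
               "pfs2_months", "pfs2_event", "pfs1_months")
)

empty_cohort_table <- function(which) {
  cols <- .COHORT_COLUMNS[[which]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  num <- intersect(cols, c("pos", "vaf", "context_channel", "pfs2_months",
                           "pfs1_months"))
  for (cl in num) df[[cl]] <- numeric(0)
  for (cl in intersect(cols, c("msi_high", "egfr_ihc_2plus", "pfs2_event")))
    df[[cl]] <- logical(0)
  df
}

#' Assemble and validate a cohort object
#'
#' @param variants,copy_number,fusions,clinical,outcomes Data frames with the
#'   schema columns (missing tables default to empty). `clinical` stores
#'   `germline_pathogenic_genes` as a comma-separated string per sample
#'   (empty string for none).
#' @param validate Run [validate_cohort()] (default `TRUE`).
#' @return An object of class `btc_cohort` (a named list of the five tables).
#' @export
new_cohort <- function(variants = NULL, copy_number = NULL, fusions = NULL,
                       clinical = NULL, outcomes = NULL, validate = TRUE) {
  co <- list(
    variants = if (is.null(variants)) empty_cohort_table("variants") else variants,
    copy_number = if (is.null(copy_number)) empty_cohort_table("copy_number") else copy_number,
    fusions = if (is.null(fusions)) empty_cohort_table("fusions") else fusions,
    clinical = if (is.null(clinical)) empty_cohort_table("clinical") else clinical,
    outcomes = if (is.null(outcomes)) empty_cohort_table("outcomes") else outcomes
  )
  class(co) <- "btc_cohort"
  if (validate) validate_cohort(co)
  co
}

#' Validate a cohort against the schema invariants
#'
#' Checks column presence, enum domains, coordinate and VAF ranges, the
#' context-channel contract (present iff ref and alt are single bases), and
#' referential integrity: every `sample_id` used by a child table must exist
#' in the clinical table. Violating rows are reported, never dropped.
#'
#' @param cohort A `btc_cohort`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "btc_cohort"))
  for (nm in names(.COHORT_COLUMNS)) {
    missing <- setdiff(.COHORT_COLUMNS[[nm]], names(cohort[[nm]]))
    if (length(missing))
      stop(sprintf("schema error: table '%s' is missing column(s): %s",
                   nm, paste(missing, collapse = ", ")), call. = FALSE)
  }
  v <- cohort$variants
  if (nrow(v)) {
    bad <- which(!(v$variant_class %in% .VARIANT_CLASSES))
    if (length(bad))
      stop(sprintf("invalid variant_class in variant row(s): %s",
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    if (any(v$pos < 1))
      stop("variant pos must be >= 1 (1-based coordinates)", call. = FALSE)
    if (any(v$ref == v$alt))
      stop("variant ref must differ from alt", call. = FALSE)
    ok_vaf <- is.na(v$vaf) | (v$vaf >= 0 & v$vaf <= 1)
    if (!all(ok_vaf))
      stop(sprintf("vaf outside [0,1] in variant row(s): %s",
                   paste(utils::head(which(!ok_vaf), 5), collapse = ", ")),
           call. = FALSE)
    is_snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L &
      v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T")
    bad_ch <- which(is_snv != !is.na(v$context_channel))
    if (length(bad_ch))
      stop(sprintf(paste0("context_channel must be present exactly for ",
                          "single-base substitutions; offending row(s): %s"),
                   paste(utils::head(bad_ch, 5), collapse = ", ")), call. = FALSE)
    ch <- v$context_channel[!is.na(v$context_channel)]
    if (length(ch) && any(ch < 0 | ch > 95 | ch != floor(ch)))
      stop("context_channel must be an integer in 0..95", call. = FALSE)
  }
  cn <- cohort$copy_number
  if (nrow(cn) && any(!(cn$cna_type %in% c("amplification", "deletion"))))
    stop("cna_type must be 'amplification' or 'deletion'", call. = FALSE)
  fu <- cohort$fusions
  if (nrow(fu) && any(fu$gene_5p == fu$gene_3p))
    warning("fusion(s) with identical 5' and 3' gene (intragenic rearrangement) retained",
            call. = FALSE)
  cl <- cohort$clinical
  if (nrow(cl)) {
    if (anyDuplicated(cl$sample_id))
      stop("duplicate sample_id in clinical table", call. = FALSE)
    if (any(!(cl$subtype %in% .SUBTYPES)) || any(is.na(cl$subtype)))
      stop("clinical subtype must be one of ICC/ECC/GBC", call. = FALSE)
    if (any(!(cl$platform %in% .PLATFORMS)) || any(is.na(cl$platform)))
      stop("clinical platform must be WES or TPS", call. = FALSE)
    if (any(!(cl$stage %in% .STAGES)))
      stop("clinical stage must be one of I/II/III_IV/unknown", call. = FALSE)
    if (any(!(cl$hepatitis %in% .HEPATITIS)))
      stop("clinical hepatitis must be positive/negative/unknown", call. = FALSE)
  }
  ou <- cohort$outcomes
  if (nrow(ou)) {
    if (any(!(ou$best_response %in% .RESPONSES)))
      stop("best_response must be one of CR/PR/SD/PD", call. = FALSE)
    if (any(!is.na(ou$pfs2_months) & ou$pfs2_months <= 0) ||
        any(!is.na(ou$pfs1_months) & ou$pfs1_months <= 0))
      stop("PFS durations must be positive", call. = FALSE)
  }
  known <- cl$sample_id
  for (nm in c("variants", "copy_number", "fusions")) {
    ids <- unique(cohort[[nm]]$sample_id)
    orphans <- setdiff(ids, known)
    if (length(orphans))
      stop(sprintf("referential error: table '%s' references sample_id(s) absent from clinical: %s",
                   nm, paste(utils::head(orphans, 10), collapse = ", ")),
           call. = FALSE)
  }
  orphans <- setdiff(unique(ou$patient_id), known)
  if (length(orphans))
    stop(sprintf("referential error: outcomes references patient_id(s) absent from clinical: %s",
                 paste(utils::head(orphans, 10), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.btc_cohort <- function(x, ...) {
  cat("<btc_cohort>\n")
  cat(sprintf("  samples:      %d\n", nrow(x$clinical)))
  cat(sprintf("  variants:     %d\n", nrow(x$variants)))
  cat(sprintf("  copy number:  %d\n", nrow(x$copy_number)))
  cat(sprintf("  fusions:      %d\n", nrow(x$fusions)))
  cat(sprintf("  outcomes:     %d\n", nrow(x$outcomes)))
  invisible(x)
}

.write_tsv <- function(df, path) {
  out <- df
  for (cl in names(out)) {
    if (is.logical(out[[cl]])) {
      out[[cl]] <- ifelse(is.na(out[[cl]]), "", tolower(as.character(out[[cl]])))
    } else if (is.numeric(out[[cl]])) {
      out[[cl]] <- ifelse(is.na(out[[cl]]), "",
                          format(out[[cl]], trim = TRUE, scientific = FALSE, digits = 15))
    } else {
      out[[cl]] <- ifelse(is.na(out[[cl]]), "", as.character(out[[cl]]))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# btcprof cohort table; coordinates 1-based inclusive; missing = empty; booleans true/false",
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", eol = "\n")
}

.read_tsv <- function(path, which) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "")
  cols <- .COHORT_COLUMNS[[which]]
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[, cols, drop = FALSE]
  template <- empty_cohort_table(which)
  for (cl in cols) {
    if (is.numeric(template[[cl]])) {
      df[[cl]] <- suppressWarnings(as.numeric(ifelse(df[[cl]] == "", NA, df[[cl]])))
    } else if (is.logical(template[[cl]])) {
      df[[cl]] <- c(true = TRUE, false = FALSE)[ifelse(df[[cl]] == "", NA, df[[cl]])]
      names(df[[cl]]) <- NULL
    } else {
      df[[cl]] <- ifelse(df[[cl]] == "" &
                           cl %in% c("cytoband", "matched_target"), NA, df[[cl]])
    }
  }
  df
}

#' Write a cohort to a directory of TSV files
#'
#' Rows are sorted deterministically (sample, then chrom/pos or gene) and the
#' column order is fixed, so the same cohort always serializes to identical
#' bytes; [read_cohort()] round-trips the result exactly.
#'
#' @param cohort A validated `btc_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  co <- cohort
  o <- order(co$variants$sample_id, co$variants$chrom, co$variants$pos,
             co$variants$gene, co$variants$alt)
  co$variants <- co$variants[o, , drop = FALSE]
  co$copy_number <- co$copy_number[order(co$copy_number$sample_id,
                                         co$copy_number$gene,
                                         co$copy_number$cna_type), , drop = FALSE]
  co$fusions <- co$fusions[order(co$fusions$sample_id, co$fusions$gene_5p,
                                 co$fusions$gene_3p), , drop = FALSE]
  co$clinical <- co$clinical[order(co$clinical$sample_id), , drop = FALSE]
  co$outcomes <- co$outcomes[order(co$outcomes$patient_id), , drop = FALSE]
  paths <- character(0)
  for (nm in names(.COHORT_FILES)) {
    p <- file.path(dir, .COHORT_FILES[[nm]])
    .write_tsv(co[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read a cohort from a directory of TSV files
#'
#' @param dir Directory containing the five cohort tables as written by
#'   [write_cohort()].
#' @param validate Cross-validate after reading (default `TRUE`).
#' @return A `btc_cohort`.
#' @export
read_cohort <- function(dir, validate = TRUE) {
  tabs <- list()
  for (nm in names(.COHORT_FILES)) {
    p <- file.path(dir, .COHORT_FILES[[nm]])
    if (!file.exists(p)) stop(sprintf("cohort file not found: %s", p), call. = FALSE)
    tabs[[nm]] <- .read_tsv(p, nm)
  }
  do.call(new_cohort, c(tabs, list(validate = validate)))
}

#' Import a variant table using standard MAF column names
#'
#' Maps the conventional MAF headers (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Classification`) onto the package schema.
#' All variant classes are retained; downstream stages apply their own
#' counting rules.
#'
#' @param maf Data frame with MAF-style columns.
#' @param class_map Named character vector mapping
#'   `Variant_Classification` values to the package's `variant_class` enum;
#'   defaults cover the common MAF vocabulary.
#' @return A variants data frame in package schema.
#' @export
import_maf_variants <- function(maf,
                                class_map = c(
                                  Missense_Mutation = "missense",
                                  Nonsense_Mutation = "nonsense",
                                  Frame_Shift_Del = "frameshift_indel",
                                  Frame_Shift_Ins = "frameshift_indel",
                                  In_Frame_Del = "inframe_indel",
                                  In_Frame_Ins = "inframe_indel",
                                  Splice_Site = "splice",
                                  Silent = "synonymous",
                                  `5'Flank` = "other_noncoding",
                                  `3'UTR` = "other_noncoding",
                                  `5'UTR` = "other_noncoding",
                                  Intron = "other_noncoding")) {
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
            "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
            "Variant_Classification")
  missing <- setdiff(need, names(maf))
  if (length(missing))
    stop(sprintf("schema error: MAF input missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  cls <- unname(class_map[maf$Variant_Classification])
  if (any(is.na(cls)))
    stop(sprintf("unmapped Variant_Classification value(s): %s",
                 paste(unique(maf$Variant_Classification[is.na(cls)]), collapse = ", ")),
         call. = FALSE)
  data.frame(
    sample_id = as.character(maf$Tumor_Sample_Barcode),
    gene = as.character(maf$Hugo_Symbol),
    chrom = as.character(maf$Chromosome),
    pos = as.numeric(maf$Start_Position),
    ref = as.character(maf$Reference_Allele),
    alt = as.character(maf$Tumor_Seq_Allele2),
    variant_class = cls,
    vaf = if ("vaf" %in% names(maf)) as.numeric(maf$vaf) else NA_real_,
    context_channel = if ("context_channel" %in% names(maf))
      as.numeric(maf$context_channel) else NA_real_,
    stringsAsFactors = FALSE
  )
}
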