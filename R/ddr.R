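#' @title DNA damage repair (DDR) classification
#' @description Classifies samples by somatic DDR mutation status against a
#'   versioned gene-to-pathway map: TP53 plus eight non-TP53 functional
#'   families (checkpoint factors, Fanconi anemia, mismatch repair,
#'   homologous recombination, nucleotide excision repair, base excision
#'   repair, non-homologous end joining, and an "other" family). The
#'   shipped 47-gene map is an editable, partly non-canonical
#'   reconstruction (see `inst/extdata/ddr_genes.yaml`).
#' @name ddr_classification
NULL

.DDR_STATUSES <- c("wild_type", "tp53_only", "non_tp53", "both")

#' Load and validate a DDR gene-to-pathway map
#'
#' @param path YAML file mapping gene symbol to pathway name; defaults to
#'   the map shipped with the package.
#' @return Named character vector gene -> pathway.
#' @export
load_ddr_map <- function(path = system.file("extdata", "ddr_genes.yaml",
                                            package = "btcprof")) {
  raw <- yaml::read_yaml(path)
  map <- unlist(raw)
  if (anyDuplicated(names(map)))
    stop("duplicate gene in DDR map", call. = FALSE)
  if (!("TP53" %in% names(map)) || map[["TP53"]] != "TP53")
    stop("DDR map must assign TP53 to its own pathway 'TP53'", call. = FALSE)
  n_path <- length(setdiff(unique(map), "TP53"))
  if (length(map) != 47L)
    warning(sprintf("DDR map has %d genes (the curated set has 47)", length(map)),
            call. = FALSE)
  if (n_path != 8L)
    warning(sprintf("DDR map has %d non-TP53 pathways (expected 8)", n_path),
            call. = FALSE)
  map
}

#' Classify samples by DDR mutation status
#'
#' A sample is DDR-mutant iff it carries at least one counted
#' (nonsynonymous, by default) variant in a mapped gene. The four-way
#' status separates TP53-only involvement from non-TP53 pathway hits;
#' unmapped genes are ignored.
#'
#' @param variants Variants data frame.
#' @param map Gene -> pathway vector from [load_ddr_map()].
#' @param sample_ids Samples to classify; defaults to samples present.
#' @param counting_rule Variant classes that count (default the
#'   nonsynonymous set).
#' @return Data frame with `sample_id`, `status`
#'   (wild_type/tp53_only/non_tp53/both), `pathways_hit` (comma-joined).
#' @export
classify_ddr <- function(variants, map = load_ddr_map(), sample_ids = NULL,
                         counting_rule = .TMB_RULES$nonsynonymous) {
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  v <- variants[variants$variant_class %in% counting_rule &
                  variants$gene %in% names(map) &
                  variants$sample_id %in% sample_ids, , drop = FALSE]
  v$pathway <- unname(map[v$gene])
  hits <- split(v$pathway, factor(v$sample_id, levels = sample_ids))
  status <- vapply(hits, function(p) {
    p <- unique(p)
    has_tp53 <- "TP53" %in% p
    has_other <- length(setdiff(p, "TP53")) > 0
    if (!has_tp53 && !has_other) "wild_type"
    else if (has_tp53 && !has_other) "tp53_only"
    else if (!has_tp53) "non_tp53"
    else "both"
  }, character(1))
  data.frame(sample_id = sample_ids,
             status = unname(status),
             pathways_hit = vapply(hits, function(p)
               paste(sort(unique(p)), collapse = ","), character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize DDR statuses across a cohort
#'
#' Besides the four-way status counts, reports the two-way attribution the
#' field prints: `n_tp53_attributed` (samples whose DDR involvement is
#' TP53 alone) and `n_non_tp53_pool` (every other mutant, i.e. samples
#' with any non-TP53 pathway hit, whether or not TP53 is also hit) — so
#' mutants = TP53-attributed + non-TP53 pool.
#'
#' @param statuses Data frame from [classify_ddr()].
#' @return List with `n`, `by_status` (named counts), `n_mutant`,
#'   `n_tp53_attributed`, `n_non_tp53_pool`, `mutant_percent`,
#'   `by_pathway` (samples per pathway).
#' @export
summarize_ddr <- function(statuses) {
  if (nrow(statuses) == 0) stop("no statuses to summarize", call. = FALSE)
  by_status <- table(factor(statuses$status, levels = .DDR_STATUSES))
  n <- nrow(statuses)
  n_mutant <- n - by_status[["wild_type"]]
  paths <- unlist(strsplit(statuses$pathways_hit[statuses$pathways_hit != ""], ","))
  list(n = n,
       by_status = c(by_status),
       n_mutant = n_mutant,
       n_tp53_attributed = by_status[["tp53_only"]],
       n_non_tp53_pool = by_status[["non_tp53"]] + by_status[["both"]],
       mutant_percent = percent_half_up(n_mutant, n),
       by_pathway = if (length(paths)) c(table(paths)) else integer(0))
}
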