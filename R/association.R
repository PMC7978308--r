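#' @title Co-occurrence / mutual-exclusivity statistics and group comparisons
#' @name association_stats
NULL

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities (margins
#' fixed) of all tables no more probable than the observed one — the
#' convention used by `stats::fisher.test`, which performs the computation
#' here. The odds ratio is the sample cross-product `ad/bc` (not the
#' conditional MLE): `Inf` when `bc = 0` and `ad > 0`, `0` when `ad = 0`
#' and `bc > 0`, `NaN` when both vanish. Set `haldane = TRUE` to add 0.5 to
#' every cell of a table containing a zero before forming the ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive sum.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to the odds
#'   ratio (the p-value is never corrected).
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(table, haldane = FALSE) {
  if (!is.matrix(table) || !all(dim(table) == c(2, 2)))
    stop("table must be a 2x2 matrix", call. = FALSE)
  if (any(table < 0) || any(table != floor(table)) || any(!is.finite(table)))
    stop("table entries must be non-negative integers", call. = FALSE)
  if (sum(table) == 0) stop("table total must be positive", call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (haldane && any(table == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  p <- stats::fisher.test(table)$p.value
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`: step-up
#' q-values, monotone in the sorted p-values, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Pairwise gene co-occurrence / mutual-exclusivity tests
#'
#' For every unordered pair of the requested genes, forms the 2x2 table of
#' mutated/wild-type sample counts, applies the two-sided Fisher test, and
#' adjusts across all pairs by Benjamini-Hochberg. A pair is called
#' `co_occurrent` when OR > 1 and q < `fdr`, `exclusive` when OR < 1 and
#' q < `fdr`, otherwise `none`.
#'
#' @param binary_matrix Logical gene x sample matrix of mutation indicators
#'   (rownames are gene symbols).
#' @param genes Genes to test (>= 2); each must be a row of the matrix.
#' @param fdr FDR cutoff for direction calls (default 0.05).
#' @return Data frame of class `pairwise_gene_tests`, one row per pair,
#'   with the 2x2 cells (`n_both`, `n_a_only`, `n_b_only`, `n_neither`),
#'   `odds_ratio`, `p_value`, `q_value`, `direction`.
#' @export
pairwise_gene_tests <- function(binary_matrix, genes = rownames(binary_matrix),
                                fdr = 0.05) {
  if (length(genes) < 2) stop("need at least 2 genes", call. = FALSE)
  absent <- setdiff(genes, rownames(binary_matrix))
  if (length(absent))
    stop(sprintf("gene(s) absent from matrix: %s", paste(absent, collapse = ", ")),
         call. = FALSE)
  m <- binary_matrix[genes, , drop = FALSE]
  storage.mode(m) <- "logical"
  pairs <- utils::combn(genes, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    a <- m[ga, ]; b <- m[gb, ]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                  nrow = 2, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    data.frame(gene_a = ga, gene_b = gb,
               n_both = tab[1, 1], n_a_only = tab[1, 2],
               n_b_only = tab[2, 1], n_neither = tab[2, 2],
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- ifelse(out$q_value < fdr & !is.nan(out$odds_ratio) & out$odds_ratio > 1,
                          "co_occurrent",
                          ifelse(out$q_value < fdr & !is.nan(out$odds_ratio) & out$odds_ratio < 1,
                                 "exclusive", "none"))
  class(out) <- c("pairwise_gene_tests", "data.frame")
  out
}

#' Welch two-sample t-test between two groups
#'
#' Unpaired two-tailed comparison with the Welch unequal-variance
#' correction, used e.g. to compare TMB between DDR-mutant and wild-type
#' patients. Degenerate case: if both groups are constant with equal means
#' the statistic is 0 and p = 1.
#'
#' @param values Numeric vector.
#' @param groups Factor/character vector with exactly two levels, aligned
#'   with `values`; each group needs n >= 2.
#' @return List with `t_statistic`, `p_value`, `df`, `group_means` (named).
#' @export
group_tmb_test <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  sp <- split(values, groups)
  if (any(vapply(sp, length, 1L) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  means <- vapply(sp, mean, 1.0)
  se2 <- sum(vapply(sp, function(v) stats::var(v) / length(v), 1.0))
  if (se2 == 0) {
    delta <- diff(means)
    if (delta == 0)
      return(list(t_statistic = 0, p_value = 1, df = NA_real_,
                  group_means = means))
    return(list(t_statistic = sign(delta) * Inf, p_value = 0, df = NA_real_,
                group_means = means))
  }
  tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), group_means = means)
}

#' Binary gene-by-sample mutation indicator matrix
#'
#' @param variants Variants data frame.
#' @param genes Genes (rows); defaults to all genes seen.
#' @param sample_ids Samples (columns); defaults to all samples seen.
#' @param nonsynonymous_only Count only protein-altering classes plus TERT
#'   promoter (default `TRUE`).
#' @return Logical matrix genes x samples.
#' @export
mutation_indicator_matrix <- function(variants, genes = NULL, sample_ids = NULL,
                                      nonsynonymous_only = TRUE) {
  v <- variants
  if (nonsynonymous_only)
    v <- v[v$variant_class %in% c(.TMB_RULES$nonsynonymous, "TERT_promoter"), ,
           drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(v$gene))
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  m <- matrix(FALSE, nrow = length(genes), ncol = length(sample_ids),
              dimnames = list(genes, sample_ids))
  v <- v[v$gene %in% genes & v$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(v)) m[cbind(v$gene, v$sample_id)] <- TRUE
  m
}
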