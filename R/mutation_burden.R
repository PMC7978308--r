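#' @title Tumor mutation burden and hypermutation calling
#' @name mutation_burden
NULL

# platform-specific hypermutation cutoffs (Mut/Mb), boundary inclusive
.HYPERMUTATION_THRESHOLDS <- c(WES = 9.36, TPS = 16.1)

.TMB_RULES <- list(
  nonsynonymous = c("missense", "nonsense", "frameshift_indel",
                    "inframe_indel", "splice"),
  nonsynonymous_snv = c("missense", "nonsense", "splice"),
  all = .VARIANT_CLASSES
)

#' Compute tumor mutation burden for one or more samples
#'
#' TMB = counted mutations / sequenced region size (Mut/Mb). The default
#' counting rule includes nonsynonymous SNVs and small indels and excludes
#' synonymous and noncoding classes; the rule is configurable because panel
#' conventions differ. An optional VAF floor drops low-fraction calls before
#' counting (variants with missing VAF are retained).
#'
#' @param variants Variants data frame (package schema); may cover several
#'   samples.
#' @param region_size_mb Sequenced target size in megabases (> 0). Either a
#'   single value or a named vector keyed by `sample_id`.
#' @param counting_rule One of `"nonsynonymous"` (default),
#'   `"nonsynonymous_snv"`, `"all"`.
#' @param sample_ids Samples to report; defaults to those present in
#'   `variants`. Samples with no variants get TMB 0.
#' @param min_vaf Optional VAF floor in \[0,1\].
#' @return Data frame with `sample_id`, `n_counted_mutations`,
#'   `region_size_mb`, `tmb`.
#' @export
compute_tmb <- function(variants, region_size_mb,
                        counting_rule = c("nonsynonymous", "nonsynonymous_snv", "all"),
                        sample_ids = NULL, min_vaf = NULL) {
  counting_rule <- match.arg(counting_rule)
  if (any(region_size_mb <= 0) || !is.numeric(region_size_mb))
    stop("region_size_mb must be > 0", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  keep <- variants$variant_class %in% .TMB_RULES[[counting_rule]]
  if (!is.null(min_vaf))
    keep <- keep & (is.na(variants$vaf) | variants$vaf >= min_vaf)
  counts <- table(factor(variants$sample_id[keep], levels = sample_ids))
  n <- as.integer(counts)
  mb <- if (!is.null(names(region_size_mb))) {
    miss <- setdiff(sample_ids, names(region_size_mb))
    if (length(miss))
      stop(sprintf("no region size for sample(s): %s",
                   paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
    unname(region_size_mb[sample_ids])
  } else rep(region_size_mb, length(sample_ids))
  data.frame(sample_id = sample_ids, n_counted_mutations = n,
             region_size_mb = mb, tmb = n / mb, stringsAsFactors = FALSE)
}

#' Call hypermutation from TMB and sequencing platform
#'
#' Applies the platform-specific thresholds: WES >= 9.36 Mut/Mb,
#' targeted panel sequencing (TPS) >= 16.1 Mut/Mb; the boundary is
#' inclusive. Vectorized over samples.
#'
#' @param tmb Numeric TMB values (Mut/Mb, >= 0).
#' @param platform Character vector, `"WES"` or `"TPS"` (recycled).
#' @return Logical vector of hypermutation calls.
#' @export
call_hypermutation <- function(tmb, platform) {
  if (any(tmb < 0, na.rm = TRUE)) stop("tmb must be >= 0", call. = FALSE)
  if (any(!(platform %in% names(.HYPERMUTATION_THRESHOLDS))))
    stop("platform must be 'WES' or 'TPS'", call. = FALSE)
  unname(tmb >= .HYPERMUTATION_THRESHOLDS[platform])
}

#' Squared Pearson correlation between paired measurements
#'
#' Used to quantify cross-platform concordance of per-sample statistics
#' (e.g. TMB measured by both WES and a targeted panel on the same tumors).
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return R-squared in \[0,1\].
#' @export
platform_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: concordance undefined", call. = FALSE)
  stats::cor(x, y)^2
}
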