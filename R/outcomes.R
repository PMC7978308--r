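#' @title Therapy outcome evaluation
#' @description RECIST response coding, objective response rate,
#'   Kaplan-Meier progression-free survival and the PFS2/PFS1 benefit rule
#'   used in molecular-tumor-board umbrella settings: PFS on the matched
#'   therapy (PFS2) divided by PFS on the immediately prior unmatched line
#'   (PFS1), with a ratio >= 1.3 counted as therapeutic benefit
#'   (Von Hoff criterion).
#' @name outcomes
NULL

#' Percent with half-up rounding
#'
#' Rounds `100 * num / den` half-up (so 26.0869 -> 26.1 at one decimal),
#' matching clinical-report conventions rather than R's banker's rounding.
#'
#' @param num,den Numerator and denominator (den > 0).
#' @param digits Decimal places (default 1).
#' @return Numeric percent.
#' @export
percent_half_up <- function(num, den, digits = 1) {
  if (any(den <= 0)) stop("denominator must be positive", call. = FALSE)
  scale <- 10^digits
  floor(100 * num / den * scale + 0.5 + 1e-9) / scale
}

#' Responder coding and objective response rate
#'
#' A responder has best RECIST response CR or PR; ORR is the responder
#' fraction of all treated patients, reported as a half-up one-decimal
#' percent.
#'
#' @param outcomes Outcomes data frame with `best_response` in CR/PR/SD/PD.
#' @return List with `responders` (logical vector), `n_responders`,
#'   `n_treated`, `orr_percent`.
#' @export
classify_response_and_orr <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("no treated patients", call. = FALSE)
  if (any(!(outcomes$best_response %in% .RESPONSES)))
    stop("best_response must be one of CR/PR/SD/PD", call. = FALSE)
  resp <- outcomes$best_response %in% c("CR", "PR")
  list(responders = resp,
       n_responders = sum(resp),
       n_treated = nrow(outcomes),
       orr_percent = percent_half_up(sum(resp), nrow(outcomes)))
}

#' PFS2/PFS1 ratio and benefit classification
#'
#' Adds `ratio = pfs2_months / pfs1_months` and `benefit = ratio >= 1.3`
#' (boundary inclusive). Both are `NA` when PFS1 is missing; such patients
#' are excluded from the benefit denominator. Censored PFS2 durations are
#' excluded from the ratio by default (`censored_ratio = FALSE`) with the
#' count reported, since a censored PFS2 only bounds the ratio from below.
#'
#' @param outcomes Outcomes data frame with `pfs2_months`, `pfs2_event`
#'   (TRUE = progression observed), `pfs1_months` (NA when unmeasurable).
#' @param censored_ratio Include censored PFS2 in the ratio (default FALSE).
#' @return List with the augmented `outcomes` table, `n_ratio_defined`,
#'   `n_pfs1_missing`, `n_pfs2_censored_excluded`, `n_benefit`,
#'   `benefit_percent` (over ratio-defined patients; NA if none).
#' @export
pfs_ratio_benefit <- function(outcomes, censored_ratio = FALSE) {
  ou <- outcomes
  if (any(!is.na(ou$pfs2_months) & ou$pfs2_months <= 0) ||
      any(!is.na(ou$pfs1_months) & ou$pfs1_months <= 0))
    stop("PFS durations must be positive", call. = FALSE)
  eligible <- !is.na(ou$pfs1_months)
  censored <- if ("pfs2_event" %in% names(ou)) !ou$pfs2_event else rep(FALSE, nrow(ou))
  n_cens_excl <- 0L
  if (!censored_ratio) {
    n_cens_excl <- sum(eligible & censored)
    eligible <- eligible & !censored
  }
  ou$ratio <- ifelse(eligible, ou$pfs2_months / ou$pfs1_months, NA_real_)
  ou$benefit <- ifelse(eligible, ou$ratio >= 1.3, NA)
  n_def <- sum(eligible)
  list(outcomes = ou,
       n_ratio_defined = n_def,
       n_pfs1_missing = sum(is.na(outcomes$pfs1_months)),
       n_pfs2_censored_excluded = n_cens_excl,
       n_benefit = sum(ou$benefit, na.rm = TRUE),
       benefit_percent = if (n_def > 0)
         percent_half_up(sum(ou$benefit, na.rm = TRUE), n_def) else NA_real_)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit`; ties are handled events-before-censorings at
#' equal times (the product-limit convention). The median is the smallest
#' time at which the survival estimate drops to 0.5 or below, `NA` if the
#' curve never reaches 0.5. The median confidence interval is
#' Brookmeyer-Crowley on the log-log scale (survfit default).
#'
#' @param times Positive durations (months).
#' @param events Logical/0-1 event indicators (TRUE = event observed).
#' @return List of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `median`, `median_ci` (95% by log-log transform), `fit` (the survfit
#'   object).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("no observations", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  med <- if (any(fit$surv <= 0.5 + 1e-12)) min(fit$time[fit$surv <= 0.5 + 1e-12]) else NA_real_
  tab <- summary(fit)$table
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event, median = med,
              median_ci = c(lower = unname(tab["0.95LCL"]),
                            upper = unname(tab["0.95UCL"])),
              fit = fit)
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d times, median %s\n",
              length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic via
#' `survival::survdiff`. If no events occurred in either group the
#' statistic is 0 and p = 1 by convention (the test carries no
#' information).
#'
#' @param times Positive durations.
#' @param events Logical event indicators.
#' @param groups Two-level grouping vector.
#' @return List with `chi_square`, `p_value`.
#' @export
logrank <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two non-empty groups required", call. = FALSE)
  events <- as.logical(events)
  if (!any(events)) return(list(chi_square = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(chi_square = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
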