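mkout <- function(best, pfs2 = 6, event = TRUE, pfs1 = NA_real_) {
  if (length(best) == 0) return(empty_cohort_table("outcomes"))
  data.frame(patient_id = sprintf("P%03d", seq_along(best)),
             matched_target = NA_character_, best_response = best,
             pfs2_months = pfs2, pfs2_event = event, pfs1_months = pfs1,
             stringsAsFactors = FALSE)
}

test_that("ORR counts CR/PR responders with half-up percent rounding", {
  out <- mkout(rep(c("CR", "PR", "SD", "PD"), c(2, 10, 20, 14)))
  res <- classify_response_and_orr(out)
  expect_equal(res$n_responders, 12)
  expect_equal(res$n_treated, 46)
  expect_equal(res$orr_percent, 26.1)
  expect_equal(classify_response_and_orr(mkout(rep("SD", 5)))$orr_percent, 0)
  expect_equal(classify_response_and_orr(mkout(rep("CR", 5)))$orr_percent, 100)
  expect_error(classify_response_and_orr(mkout(character(0))), "no treated")
  # rounding-aware complement: responder and non-responder rates cover 100
  expect_equal(res$orr_percent +
                 percent_half_up(res$n_treated - res$n_responders,
                                 res$n_treated), 100, tolerance = 0.1)
})

test_that("PFS2/PFS1 benefit uses the inclusive 1.3 threshold and explicit denominators", {
  out <- mkout(c("PR", "SD", "SD"), pfs2 = c(6.5, 5, 4),
               pfs1 = c(5, 5, NA))
  res <- pfs_ratio_benefit(out)
  expect_equal(res$outcomes$ratio, c(1.3, 1.0, NA))
  expect_equal(res$outcomes$benefit, c(TRUE, FALSE, NA))
  expect_equal(res$n_ratio_defined, 2)
  expect_equal(res$n_pfs1_missing, 1)
  expect_equal(res$benefit_percent, 50)
  # censored PFS2 excluded from the ratio by default, includable by flag
  outc <- mkout(c("SD", "SD"), pfs2 = c(10, 10), event = c(FALSE, TRUE),
                pfs1 = c(5, 5))
  resc <- pfs_ratio_benefit(outc)
  expect_equal(resc$n_pfs2_censored_excluded, 1)
  expect_equal(resc$n_ratio_defined, 1)
  expect_equal(pfs_ratio_benefit(outc, censored_ratio = TRUE)$n_ratio_defined, 2)
  bad <- mkout("SD", pfs2 = -1)
  expect_error(pfs_ratio_benefit(bad), "positive")
})

test_that("Kaplan-Meier curve matches the hand-computed product limit", {
  # observations: 3+, 4, 5, 5, 8+, 9
  times <- c(3, 4, 5, 5, 8, 9)
  events <- c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  km <- km_estimate(times, events)
  surv_at <- function(t) km$surv[match(t, km$time)]
  expect_equal(surv_at(4), 4 / 5)             # 5 at risk after the censor at 3
  expect_equal(surv_at(5), 4 / 5 * 2 / 4)     # two events among 4 at risk
  expect_equal(surv_at(9), 0)                 # final event exhausts the risk set
  expect_equal(km$median, 5)
  # single event
  km1 <- km_estimate(3, TRUE)
  expect_equal(km1$surv, 0)
  expect_equal(km1$median, 3)
  # all censored: flat curve, median undefined
  km2 <- km_estimate(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km2$median))
  expect_error(km_estimate(numeric(0), logical(0)), "no observations")
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)), "positive")
  # monotone non-increasing from 1
  set.seed(13)
  km3 <- km_estimate(stats::rexp(100, 0.2), stats::runif(100) < 0.7)
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_lte(max(km3$surv), 1)
})

test_that("log-rank test behaves on degenerate and planted-effect inputs", {
  times <- c(2, 3, 5, 7); events <- c(TRUE, TRUE, FALSE, TRUE)
  res <- logrank(rep(times, 2), rep(events, 2), rep(c("a", "b"), each = 4))
  expect_equal(res$chi_square, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  # no events at all: statistic 0 by convention
  res0 <- logrank(c(1, 2, 3, 4), rep(FALSE, 4), c("a", "a", "b", "b"))
  expect_equal(res0$chi_square, 0)
  expect_equal(res0$p_value, 1)
  expect_error(logrank(1:4, rep(TRUE, 4), rep("a", 4)), "two")
  # planted hazard ratio 3 is detected
  set.seed(29)
  t1 <- stats::rexp(200, 1); t2 <- stats::rexp(200, 3)
  res3 <- logrank(c(t1, t2), rep(TRUE, 400), rep(c("g1", "g2"), each = 200))
  expect_lt(res3$p_value, 0.001)
})

test_that("percent formatting rounds half-up like the clinical reports", {
  expect_equal(percent_half_up(12, 46), 26.1)
  expect_equal(percent_half_up(21, 37), 56.8)
  expect_equal(percent_half_up(96, 803), 12.0)
  expect_equal(percent_half_up(1, 800), 0.1)
  expect_equal(percent_half_up(5, 1000), 0.5)  # exact .05 rounds up
  expect_error(percent_half_up(1, 0), "positive")
})
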