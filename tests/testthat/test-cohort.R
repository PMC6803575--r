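test_that("group percentages use exact half-up arithmetic", {
  counts <- c(chr21_multiplication = 56, etv6_runx1 = 34, iamp21 = 3,
              none = 142)
  cohort <- group_percentages(counts, "cohort")
  expect_equal(unname(cohort["none"]), 60.43)
  expect_equal(unname(cohort["etv6_runx1"]), 14.47)
  expect_equal(unname(cohort["iamp21"]), 1.28)
  expect_equal(unname(sum(counts) - counts["none"]), 93)

  aberrant <- group_percentages(counts, "aberrant")
  expect_false("none" %in% names(aberrant))
  expect_equal(unname(aberrant["chr21_multiplication"]), 60.22)
  expect_equal(unname(aberrant["etv6_runx1"]), 36.56)
  expect_equal(unname(aberrant["iamp21"]), 3.23)

  expect_equal(unname(group_percentages(c(a = 1), "cohort")), 100.00)
  expect_equal(unname(group_percentages(c(gain = 40, other = 20))["gain"]),
               66.67)
  expect_error(group_percentages(c(a = 0, b = 0)), "zero")
  expect_error(group_percentages(c(1, 2)), "named")
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("group medians report median and interpolated IQR per group", {
  # nine samples across three groups, constructed DQ profiles
  meds <- c(2.30, 2.81, 3.38, 1.0, 1.0, 1.0, 1.0, 1, 2, 3, 4)
  groups <- c(rep("iamp21", 3), rep("none", 4), rep("etv6_runx1", 4))
  dq <- sapply(meds, function(m) flat_dq(value = m))
  colnames(dq) <- sprintf("S%02d", seq_along(meds))
  truth <- data.frame(sample_id = colnames(dq), group = groups)

  gm <- group_medians(dq, p327, truth, "all")
  expect_equal(gm$median[gm$group == "iamp21"], 2.81)
  expect_equal(gm$iqr_lo[gm$group == "iamp21"], 2.555)  # type-7 interpolation
  expect_equal(gm$median[gm$group == "none"], 1.0)
  expect_equal(gm$median[gm$group == "etv6_runx1"], 2.5)  # even-count rule
  # empty group carries n = 0 and absent statistics
  expect_equal(gm$n[gm$group == "chr21_multiplication"], 0L)
  expect_true(is.na(gm$median[gm$group == "chr21_multiplication"]))
  expect_true(all(gm$iqr_lo <= gm$median & gm$median <= gm$iqr_hi,
                  na.rm = TRUE))
})

test_that("Kruskal-Wallis agrees with the closed form computed from ranks", {
  values <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(5, 6, 7, 8))
  res <- suppressWarnings(compare_groups(values))
  expect_equal(res$kw_statistic, kw_closed_form(values), tolerance = 1e-12)

  tied <- list(a = c(1, 1, 2, 3), b = c(3, 3, 4, 5))
  res2 <- compare_groups(tied)
  expect_equal(res2$kw_statistic, kw_closed_form(tied), tolerance = 1e-12)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_lt(compare_groups(same)$kw_statistic, 1e-12)
})

test_that("pairwise Mann-Whitney is exact by enumeration on tiny groups", {
  # completely separated triples: the most extreme of choose(6,3) = 20
  # assignments on each side, hence two-sided p = 2/20 = 0.1
  res <- compare_groups(list(a = c(1, 1, 1), b = c(10, 10, 10)))
  expect_equal(res$pairwise$mw_p, 0.1)
  expect_equal(res$pairwise$u_statistic, 0)

  # on untied data the enumeration must agree with the exact distribution
  # implemented independently in stats::wilcox.test
  set.seed(99)
  for (i in 1:5) {
    x <- sample(1:100, 6)
    y <- sample(1:100, 7) + 0.5  # offset grid guarantees no cross-group ties
    ours <- compare_groups(list(x = x, y = y))$pairwise$mw_p
    expect_equal(ours, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # Holm adjustment covers all pairs
  res3 <- compare_groups(list(a = 1:4, b = 2:5, c = 20:23))
  expect_equal(nrow(res3$pairwise), 3L)
  expect_equal(res3$pairwise$mw_p_holm,
               stats::p.adjust(res3$pairwise$mw_p, "holm"))

  expect_warning(compare_groups(list(a = 1:5, b = 2:6, tiny = 3)), "fewer")
  expect_error(suppressWarnings(compare_groups(list(a = 1:5, tiny = 3))),
               "at least 2")
})

test_that("group comparison holds its type-I error on null data", {
  set.seed(2026)
  reject <- replicate(200, {
    g1 <- stats::rnorm(50); g2 <- stats::rnorm(50)
    compare_groups(list(a = g1, b = g2))$kw_p < 0.05
  })
  expect_gte(mean(!reject), 0.9)
})

test_that("concordance counts false calls and iAMP21 sensitivity", {
  # constructed cohort mirroring the published contingency: 56 gain samples
  # with 10 medians in the normal window; 142 no-aberration samples with 22
  # duplication-range calls; 3 iAMP21, all detected
  gain_med <- c(rep(1.0, 10), rep(1.47, 46))
  none_med <- c(rep(1.40, 22), rep(1.0, 120))
  iamp_med <- rep(2.81, 3)
  calls <- data.frame(
    sample_id = sprintf("S%03d", 1:201),
    category = c(ifelse(gain_med < 1.15, "no_chr21_aberration",
                        "chr21_multiplication"),
                 ifelse(none_med >= 1.35, "chr21_multiplication",
                        "no_chr21_aberration"),
                 rep("iamp21", 3)),
    median_dq_all = c(gain_med, none_med, iamp_med),
    median_dq_runx1 = c(gain_med, none_med, iamp_med))
  truth <- data.frame(sample_id = calls$sample_id,
                      group = c(rep("chr21_multiplication", 56),
                                rep("none", 142), rep("iamp21", 3)))
  rep <- concordance(calls, truth)
  expect_equal(rep$fn_chr21_gain$count, 10)
  expect_equal(rep$fn_chr21_gain$rate_percent, 17.86)
  expect_equal(rep$fp_none$count, 22)
  expect_equal(rep$fp_none$rate_percent, 15.49)
  expect_equal(rep$iamp21_sensitivity, 1.0)

  # a perfectly called cohort has no errors
  perfect <- calls
  perfect$category <- c(rep("chr21_multiplication", 56),
                        rep("no_chr21_aberration", 142), rep("iamp21", 3))
  perfect$median_dq_all <- c(rep(1.47, 56), rep(1.0, 142), rep(2.81, 3))
  rep2 <- concordance(perfect, truth)
  expect_equal(rep2$fn_chr21_gain$count, 0)
  expect_equal(rep2$fp_none$count, 0)
  expect_equal(rep2$call_accuracy_percent, 100)

  expect_error(concordance(calls[-1, ], truth), "different samples")
  expect_error(concordance(calls, transform(truth, group = "oops")),
               "unknown truth group")
})
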