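test_that("expected DQ follows the blast-dilution mixture", {
  expect_equal(expected_dq(2, 0.3), 1.0)     # diploid identity at any purity
  expect_equal(expected_dq(2, 1.0, 0.5), 1.0)
  expect_equal(expected_dq(3, 1.0), 1.5)     # pure trisomy
  expect_equal(expected_dq(3, 0.4), 1.2)     # diluted trisomy: borderline gap
  expect_equal(expected_dq(10, 0.9), 4.6)
  expect_equal(expected_dq(0, 1.0), 0.0)     # homozygous deletion
  expect_equal(expected_dq(3, 0.5, 0.5), 1.125)
  expect_error(expected_dq(3, 1.5), "\\[0, 1\\]")
  expect_error(expected_dq(-1, 0.5), "non-negative")
  expect_error(expected_dq(2.5, 0.5), "integer")
})

test_that("simulation configs validate their invariants", {
  expect_silent(sim_config())
  expect_error(sim_config(group_proportions = c(none = 0.5,
                                                chr21_multiplication = 0.4,
                                                etv6_runx1 = 0.2,
                                                iamp21 = 0.1)), "sum to 1")
  expect_error(sim_config(extra_copies_probs = rep(0.2, 4)), "1..5")
  expect_error(sim_config(noise_sigma = -1), "non-negative")
  expect_error(sim_config(blast_range = c(50, 40)), "increasing")
  # cohort-mirroring defaults: exact proportions from the 142/56/34/3 split
  cfg <- sim_config()
  expect_equal(sum(cfg$group_proportions), 1, tolerance = 1e-12)
  expect_equal(unname(cfg$group_proportions["none"]), 142 / 235)
})

test_that("cohorts are reproducible bit-for-bit and fully labelled", {
  cfg <- sim_config(n_samples = 40, seed = 123)
  a <- simulate_cohort(cfg, p327)
  b <- simulate_cohort(cfg, p327)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$truth, b$truth)
  expect_equal(a$truth$sample_id, colnames(a$peaks))
  expect_true(all(a$truth$group %in% c("none", "chr21_multiplication",
                                       "etv6_runx1", "iamp21")))
  mult <- a$truth[a$truth$group == "chr21_multiplication", ]
  expect_true(all(mult$extra_chr21_copies >= 1))
  # a different seed changes the data
  expect_false(identical(
    simulate_cohort(sim_config(n_samples = 40, seed = 124), p327)$peaks,
    a$peaks))
})

test_that("noise-free simulation recovers expected DQ exactly", {
  refs <- simulate_reference_runs(4, p327, noise_sigma = 0, seed = 5)

  cfg0 <- sim_config(n_samples = 5, noise_sigma = 0,
                     group_proportions = c(none = 1, chr21_multiplication = 0,
                                           etv6_runx1 = 0, iamp21 = 0),
                     seed = 6)
  dq0 <- peaks_to_dq(simulate_cohort(cfg0, p327)$peaks, refs, p327)
  expect_true(all(abs(dq0 - 1) < 1e-12))

  # iAMP21 with 6 RUNX1 copies at full purity: block DQ 3.0, flanks 1.0
  cfg1 <- sim_config(n_samples = 3, noise_sigma = 0,
                     group_proportions = c(none = 0, chr21_multiplication = 0,
                                           etv6_runx1 = 0, iamp21 = 1),
                     runx1_copies_range = c(6L, 6L),
                     blast_range = c(100 - 1e-9, 100), seed = 7)
  dq1 <- peaks_to_dq(simulate_cohort(cfg1, p327)$peaks, refs, p327)
  blk <- probes_in_region(p327, "NCAM2", "RIPK4")$probe_id
  flank <- setdiff(rownames(dq1), blk)
  expect_true(all(abs(dq1[blk, ] - 3.0) < 1e-9))
  expect_true(all(abs(dq1[flank, ] - 1.0) < 1e-9))

  # general conservation: pipeline DQ equals expected_dq per probe
  cfg2 <- sim_config(n_samples = 10, noise_sigma = 0, seed = 8,
                     subclone_fraction = 0.7)
  coh2 <- simulate_cohort(cfg2, p327)
  dq2 <- peaks_to_dq(coh2$peaks, refs, p327)
  for (i in seq_len(ncol(dq2))) {
    t <- coh2$truth[i, ]
    f <- t$blast_percent / 100
    exp_block <- switch(t$group,
      none = 1, etv6_runx1 = 1,
      chr21_multiplication = expected_dq(2 + t$extra_chr21_copies, f, 0.7),
      iamp21 = expected_dq(t$runx1_copies, f, 0.7))
    probe_set <- if (t$group == "iamp21") blk else rownames(dq2)
    expect_true(all(abs(dq2[probe_set, i] - exp_block) < 1e-12),
                info = paste("sample", i, t$group))
  }
})

test_that("reference-run generator is diploid and seeded", {
  r0 <- simulate_reference_runs(3, p327, noise_sigma = 0, seed = 1)
  rel <- intra_sample_normalize(r0, p327)
  expect_true(all(abs(rel - rel[, 1]) < 1e-12))  # identical profiles

  # with noise, the reference mean estimates the probe-efficiency profile
  # (efficiency over median reference-probe efficiency) to within a few
  # percent per probe at n = 10
  r1 <- simulate_reference_runs(10, p327, noise_sigma = 0.05, seed = 2)
  mu <- build_reference_set(r1, p327)$per_probe_mean
  eff <- mlpa21:::probe_efficiencies(p327)
  expected <- eff / stats::median(eff[p327$probe_id[p327$is_reference]])
  expect_lt(max(abs(mu / expected - 1)), 0.1)
  expect_lt(mean(abs(mu / expected - 1)), 0.025)
  expect_error(simulate_reference_runs(2, p327), "at least 3")
})

test_that("high-purity cohorts are recovered almost perfectly", {
  cfg <- sim_config(n_samples = 150, noise_sigma = 0.05,
                    blast_range = c(85, 100), seed = 31)
  coh <- simulate_cohort(cfg, p327)
  refs <- simulate_reference_runs(10, p327, noise_sigma = 0.05, seed = 32)
  dq <- peaks_to_dq(coh$peaks, refs, p327)
  calls <- classify_cohort(dq, p327)
  rep <- concordance(calls, coh$truth)
  expect_gte(rep$call_accuracy_percent, 95)
  if (any(coh$truth$group == "iamp21"))
    expect_equal(rep$iamp21_sensitivity, 1.0)
})

test_that("false-negative fraction shrinks as blast fraction rises", {
  fractions <- sapply(c(0.2, 0.6, 1.0), function(f) {
    cfg <- sim_config(n_samples = 100, noise_sigma = 0.05,
                      group_proportions = c(none = 0, chr21_multiplication = 1,
                                            etv6_runx1 = 0, iamp21 = 0),
                      extra_copies_probs = c(1, 0, 0, 0, 0),  # trisomy only
                      blast_range = c(100 * f - 1e-6, 100 * f),
                      seed = 41)
    coh <- simulate_cohort(cfg, p327)
    refs <- simulate_reference_runs(10, p327, noise_sigma = 0.05, seed = 42)
    med <- median_dq(peaks_to_dq(coh$peaks, refs, p327), p327, "all")
    mean(med >= 0.85 & med <= 1.15)
  })
  expect_true(all(diff(fractions) <= 0))
  expect_gt(fractions[1], 0.8)     # f = 0.2: trisomy almost always masked
  expect_equal(fractions[3], 0.0)  # pure samples never in the normal window
})
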