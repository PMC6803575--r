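# Synthetic MLPA cohorts with known ground truth.
#
# The generator emulates the measurement process the caller assumes: per
# sample a diagnostic group, a blast fraction, and a per-probe copy-number
# vector; peaks are proportional to the blast-diluted copy-number ratio,
# modulated by a fixed per-probe amplification efficiency (a property of the
# probemix, shared with reference runs, so it cancels in the DQ), a random
# per-sample global scale (cancelled by intra-sample normalization), and
# independent multiplicative lognormal noise per probe.

#' Expected Dosage Quotient under blast-fraction dilution
#'
#' In a bulk bone-marrow sample only the leukemic blasts (fraction `f`)
#' carry the aberration, and within the blasts only a subclone (fraction
#' `s`) may carry it. The expected DQ at a locus of blast copy number `c`
#' is therefore the mixture \code{(1 - f*s) + f*s*(c/2)}: diploid at
#' `c = 2` regardless of purity, and pulled toward 1.0 as purity falls —
#' the mechanism behind false-negative calls in low-blast samples.
#'
#' @param copy_number Integer copy number in the aberrant cells (>= 0).
#' @param blast_fraction Blast fraction of the sample, in \[0, 1\].
#' @param subclone_fraction Fraction of blasts carrying the aberration,
#'   in \[0, 1\] (default 1, clonal).
#' @return Expected DQ (numeric, vectorized over `copy_number`).
#' @examples
#' expected_dq(3, 1.0)   # pure trisomy: 1.5
#' expected_dq(3, 0.4)   # diluted trisomy: 1.2, inside the borderline gap
#' @export
expected_dq <- function(copy_number, blast_fraction, subclone_fraction = 1) {
  if (any(!is.finite(copy_number)) || any(copy_number < 0) ||
      any(copy_number != round(copy_number)))
    fail("copy_number must be a non-negative integer")
  if (!is.numeric(blast_fraction) || any(blast_fraction < 0) ||
      any(blast_fraction > 1))
    fail("blast_fraction must lie in [0, 1]")
  if (!is.numeric(subclone_fraction) || any(subclone_fraction < 0) ||
      any(subclone_fraction > 1))
    fail("subclone_fraction must lie in [0, 1]")
  fs <- blast_fraction * subclone_fraction
  (1 - fs) + fs * (copy_number / 2)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults mirror the cohort
#' the caller was characterized on: group proportions from the 142/56/34/3
#' split of 235 samples; blast percentage from a beta distribution
#' quantile-matched to median 92.4 (IQR 84.2-96.0); 1 to 5 extra
#' chromosomes 21 with mean 1.8 for multiplication samples; iAMP21 blocks
#' spanning NCAM2..RIPK4 with 5-12 RUNX1 copies; multiplicative lognormal
#' probe noise with log-scale sd 0.05.
#'
#' @param n_samples Number of samples to simulate.
#' @param group_proportions Named proportions over the four truth groups
#'   (`none`, `chr21_multiplication`, `etv6_runx1`, `iamp21`); must sum
#'   to 1.
#' @param blast_shape1,blast_shape2 Beta shape parameters of the blast
#'   fraction.
#' @param blast_range Truncation range for the blast percentage, in percent.
#' @param extra_copies_probs Probabilities of 1..5 extra chromosomes 21 for
#'   multiplication samples.
#' @param runx1_copies_range Integer range of RUNX1 copy number in iAMP21
#'   blocks (sampled uniformly).
#' @param block_start_gene,block_end_gene Genes bounding the amplified
#'   block of iAMP21 samples.
#' @param subclone_fraction Fraction of blasts carrying the aberration.
#' @param noise_sigma Log-scale sd of the per-probe multiplicative noise.
#' @param base_intensity Mean raw peak fluorescence of a diploid probe.
#' @param seed Integer RNG seed; the cohort is bit-for-bit reproducible
#'   from the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 235,
                       group_proportions = c(none = 142, chr21_multiplication = 56,
                                             etv6_runx1 = 34, iamp21 = 3) / 235,
                       blast_shape1 = 7.89, blast_shape2 = 0.96,
                       blast_range = c(0, 100),
                       extra_copies_probs = c(0.53, 0.27, 0.11, 0.05, 0.04),
                       runx1_copies_range = c(5L, 12L),
                       block_start_gene = "NCAM2", block_end_gene = "RIPK4",
                       subclone_fraction = 1,
                       noise_sigma = 0.05,
                       base_intensity = 1000,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              group_proportions = group_proportions,
              blast_shape1 = blast_shape1, blast_shape2 = blast_shape2,
              blast_range = as.numeric(blast_range),
              extra_copies_probs = extra_copies_probs,
              runx1_copies_range = as.integer(runx1_copies_range),
              block_start_gene = block_start_gene,
              block_end_gene = block_end_gene,
              subclone_fraction = subclone_fraction,
              noise_sigma = noise_sigma,
              base_intensity = base_intensity,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  gp <- cfg$group_proportions
  if (is.null(names(gp)) || !setequal(names(gp), TRUTH_GROUPS))
    fail("group_proportions must be named over: %s",
         paste(TRUTH_GROUPS, collapse = ", "))
  if (any(gp < 0) || any(gp > 1) || abs(sum(gp) - 1) > 1e-9)
    fail("group_proportions must lie in [0, 1] and sum to 1")
  if (cfg$n_samples < 1L) fail("n_samples must be >= 1")
  if (cfg$blast_shape1 <= 0 || cfg$blast_shape2 <= 0)
    fail("beta shape parameters must be positive")
  if (length(cfg$blast_range) != 2L || cfg$blast_range[1L] < 0 ||
      cfg$blast_range[2L] > 100 || diff(cfg$blast_range) <= 0)
    fail("blast_range must be an increasing interval within [0, 100]")
  p <- cfg$extra_copies_probs
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    fail("extra_copies_probs must give probabilities for 1..5 extra copies summing to 1")
  r <- cfg$runx1_copies_range
  if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 3L)
    fail("runx1_copies_range must be an increasing integer range with lower bound >= 3")
  if (cfg$subclone_fraction < 0 || cfg$subclone_fraction > 1)
    fail("subclone_fraction must lie in [0, 1]")
  if (cfg$noise_sigma < 0) fail("noise_sigma must be non-negative")
  if (cfg$base_intensity <= 0) fail("base_intensity must be positive")
  invisible(cfg)
}

# Fixed per-probe amplification efficiency: a property of the probemix,
# deterministic for a given panel so that sample and reference runs share it
# (as they share the physical probemix) and it cancels exactly in the DQ.
probe_efficiencies <- function(panel, sd_log = 0.15) {
  with_seed(327L, {
    e <- exp(stats::rnorm(nrow(panel), 0, sd_log))
    stats::setNames(e, panel$probe_id)
  })
}

# Draw one blast fraction (0-1 scale) from the truncated beta.
draw_blast_fraction <- function(cfg) {
  lo <- cfg$blast_range[1L] / 100
  hi <- cfg$blast_range[2L] / 100
  # inverse-CDF sampling on the truncated range keeps this exact and cheap
  u <- stats::runif(1L, stats::pbeta(lo, cfg$blast_shape1, cfg$blast_shape2),
                    stats::pbeta(hi, cfg$blast_shape1, cfg$blast_shape2))
  stats::qbeta(u, cfg$blast_shape1, cfg$blast_shape2)
}

# Copy-number vector over target probes for one sample of a given group.
copy_vector <- function(group, cfg, panel, extra_copies, runx1_copies) {
  tgt <- target_probes(panel)
  cn <- rep(2L, nrow(tgt))
  if (group == "chr21_multiplication") {
    cn <- cn + extra_copies
  } else if (group == "iamp21") {
    block <- probes_in_region(panel, cfg$block_start_gene, cfg$block_end_gene)
    cn[tgt$probe_id %in% block$probe_id] <- runx1_copies
  }
  stats::setNames(cn, tgt$probe_id)
}

# MRD day-15 medians per group used for truth metadata only (percent).
MRD_MEDIANS <- c(none = 2.45, chr21_multiplication = 0.63,
                 etv6_runx1 = 0.30, iamp21 = 27.60)

#' Simulate a synthetic MLPA cohort
#'
#' Generates raw peak tables plus truth labels for `n_samples` bone-marrow
#' samples according to [sim_config()]. Per sample: a truth group, a blast
#' fraction, and a probe-level copy-number vector (diploid for `none` and
#' copy-neutral `etv6_runx1`; whole-chromosome gain for
#' `chr21_multiplication`; an amplified NCAM2..RIPK4 block with diploid
#' flanks for `iamp21`). Peaks are
#' `base_intensity * efficiency(probe) * scale(sample) * expected_dq(c, f, s)`
#' times lognormal noise; reference probes are always diploid. The output is
#' bit-for-bit reproducible from the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @param panel Probe panel.
#' @return List of class `synthetic_cohort` with `peaks` (all panel probes
#'   by samples), `truth` (data frame: `sample_id`, `group`,
#'   `extra_chr21_copies`, `runx1_copies`, `hyperdiploid`, `blast_percent`,
#'   `mrd_day15_percent`, `mrd_positive`), and `config`.
#' @export
simulate_cohort <- function(config, panel) {
  if (!inherits(config, "sim_config")) fail("config must be a sim_config object")
  validate_sim_config(config)
  cfg <- config
  eff <- probe_efficiencies(panel)
  tgt_ids <- target_probes(panel)$probe_id
  ref_ids <- reference_probe_ids(panel)
  with_seed(cfg$seed, {
    groups <- sample(names(cfg$group_proportions), cfg$n_samples,
                     replace = TRUE, prob = cfg$group_proportions)
    peaks <- matrix(NA_real_, nrow = nrow(panel), ncol = cfg$n_samples,
                    dimnames = list(panel$probe_id,
                                    sprintf("S%04d", seq_len(cfg$n_samples))))
    truth <- vector("list", cfg$n_samples)
    for (i in seq_len(cfg$n_samples)) {
      g <- groups[i]
      f <- draw_blast_fraction(cfg)
      extra <- if (g == "chr21_multiplication")
        sample(1:5, 1L, prob = cfg$extra_copies_probs) else NA_integer_
      rc <- if (g == "iamp21") {
        # index-based draw: sample(x, 1) on a length-1 x would resample 1:x
        vals <- seq.int(cfg$runx1_copies_range[1L], cfg$runx1_copies_range[2L])
        vals[sample.int(length(vals), 1L)]
      } else NA_integer_
      cn <- copy_vector(g, cfg, panel, extra, rc)
      edq <- expected_dq(cn, f, cfg$subclone_fraction)
      scale <- exp(stats::rnorm(1L, 0, 0.2))
      noise <- if (cfg$noise_sigma > 0)
        exp(stats::rnorm(nrow(panel), 0, cfg$noise_sigma)) else rep(1, nrow(panel))
      names(noise) <- panel$probe_id
      peaks[tgt_ids, i] <- cfg$base_intensity * eff[tgt_ids] * scale *
        edq[tgt_ids] * noise[tgt_ids]
      peaks[ref_ids, i] <- cfg$base_intensity * eff[ref_ids] * scale *
        noise[ref_ids]
      mrd <- min(100, MRD_MEDIANS[[g]] * exp(stats::rnorm(1L, 0, 1)))
      truth[[i]] <- data.frame(
        sample_id = colnames(peaks)[i], group = g,
        extra_chr21_copies = extra, runx1_copies = rc,
        hyperdiploid = identical(g, "chr21_multiplication") && !is.na(extra) &&
          extra >= 2L,
        blast_percent = 100 * f,
        mrd_day15_percent = mrd, mrd_positive = mrd >= 10)
    }
    structure(list(peaks = peaks, truth = do.call(rbind, truth),
                   config = cfg),
              class = "synthetic_cohort")
  })
}

#' Simulate healthy reference runs
#'
#' Diploid runs for [build_reference_set()], generated under the same
#' probe-efficiency and noise model as [simulate_cohort()].
#'
#' @param n Number of reference runs (>= 3).
#' @param panel Probe panel.
#' @param noise_sigma Log-scale sd of multiplicative probe noise.
#' @param seed Integer RNG seed.
#' @param base_intensity Mean diploid peak fluorescence.
#' @return Peak matrix, panel probes by `n` runs.
#' @export
simulate_reference_runs <- function(n, panel, noise_sigma = 0.05, seed = 1L,
                                    base_intensity = 1000) {
  if (n < 3L) fail("at least 3 reference runs are required (got %d)", n)
  eff <- probe_efficiencies(panel)
  with_seed(as.integer(seed), {
    peaks <- sapply(seq_len(n), function(i) {
      scale <- exp(stats::rnorm(1L, 0, 0.2))
      noise <- if (noise_sigma > 0)
        exp(stats::rnorm(nrow(panel), 0, noise_sigma)) else rep(1, nrow(panel))
      base_intensity * eff * scale * noise
    })
    dimnames(peaks) <- list(panel$probe_id, sprintf("REFRUN%02d", seq_len(n)))
    peaks
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic MLPA cohort: %d samples on %d probes (seed %d)\n",
              ncol(x$peaks), nrow(x$peaks), x$config$seed))
  print(table(x$truth$group))
  invisible(x)
}
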