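# Probe- and sample-level CNV calling from Dosage Quotients.
#
# Probe categories follow fixed DQ windows; the unnamed gaps between windows
# are reported as "borderline" rather than forced into a neighbouring
# category. Sample calls layer the iAMP21 RUNX1 rule (median RUNX1 DQ above
# 2.20) on top, with a uniform-elevation check that separates focal
# amplification from whole-chromosome gain in hyperdiploid samples.

PROBE_CATEGORIES <- c("homozygous_deletion", "heterozygous_deletion",
                      "normal", "heterozygous_duplication",
                      "homozygous_duplication", "amplification", "borderline")

GAIN_CATEGORIES <- c("heterozygous_duplication", "homozygous_duplication",
                     "amplification")

#' DQ classification thresholds
#'
#' The window bounds used for probe classification and sample calling, on
#' the DQ scale (1.0 = diploid). Defaults: normal \[0.85, 1.15\],
#' heterozygous deletion \[0.35, 0.65\], homozygous deletion below 0.35,
#' heterozygous duplication \[1.35, 1.55\], homozygous duplication
#' \[1.70, 2.20\], and iAMP21 qualification when the median RUNX1 DQ exceeds
#' 2.20. All named windows are closed; the gaps between them classify as
#' borderline. `uniform_gain_fraction` and `uniform_percentile_ratio`
#' parameterize the uniform-elevation (hyperdiploidy) check.
#'
#' @param normal_lo,normal_hi Normal window bounds.
#' @param hetdel_lo,hetdel_hi Heterozygous-deletion window bounds.
#' @param homdel_max Upper bound (exclusive) of homozygous deletion.
#' @param hetdup_lo,hetdup_hi Heterozygous-duplication window bounds.
#' @param homdup_lo,homdup_hi Homozygous-duplication window bounds.
#' @param iamp21_runx1 Strict lower bound on the median RUNX1 DQ for iAMP21.
#' @param uniform_gain_fraction Minimum fraction of target probes in a gain
#'   category for a profile to count as uniformly elevated.
#' @param uniform_percentile_ratio Maximum 90th/10th DQ percentile ratio for
#'   a profile to count as flat.
#' @return Object of class `dq_thresholds`.
#' @export
dq_thresholds <- function(normal_lo = 0.85, normal_hi = 1.15,
                          hetdel_lo = 0.35, hetdel_hi = 0.65,
                          homdel_max = 0.35,
                          hetdup_lo = 1.35, hetdup_hi = 1.55,
                          homdup_lo = 1.70, homdup_hi = 2.20,
                          iamp21_runx1 = 2.20,
                          uniform_gain_fraction = 0.9,
                          uniform_percentile_ratio = 1.5) {
  th <- list(normal_lo = normal_lo, normal_hi = normal_hi,
             hetdel_lo = hetdel_lo, hetdel_hi = hetdel_hi,
             homdel_max = homdel_max,
             hetdup_lo = hetdup_lo, hetdup_hi = hetdup_hi,
             homdup_lo = homdup_lo, homdup_hi = homdup_hi,
             iamp21_runx1 = iamp21_runx1,
             uniform_gain_fraction = uniform_gain_fraction,
             uniform_percentile_ratio = uniform_percentile_ratio)
  for (nm in names(th))
    if (!is_scalar_number(th[[nm]]) || th[[nm]] < 0)
      fail("threshold '%s' must be a single non-negative number", nm)
  chain <- c(th$homdel_max, th$hetdel_lo, th$hetdel_hi, th$normal_lo,
             th$normal_hi, th$hetdup_lo, th$hetdup_hi, th$homdup_lo,
             th$homdup_hi, th$iamp21_runx1)
  strict <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  ok <- ifelse(strict, diff(chain) > 0, diff(chain) >= 0)
  if (!all(ok))
    fail("thresholds violate the required window ordering (homdel_max <= hetdel_lo < hetdel_hi < normal_lo < normal_hi < hetdup_lo < hetdup_hi < homdup_lo < homdup_hi <= iamp21_runx1)")
  if (th$uniform_gain_fraction > 1)
    fail("uniform_gain_fraction must lie in [0, 1]")
  structure(th, class = "dq_thresholds")
}

#' Classify a DQ value into a CNV category
#'
#' Pure window lookup: each named window is closed on both ends; values in
#' the unnamed gaps (0.65-0.85, 1.15-1.35, 1.55-1.70) classify as
#' `borderline`; values above the homozygous-duplication window classify as
#' `amplification`. Ties at the shared bounds 0.35 and 2.20 resolve to the
#' lower-severity named category (heterozygous deletion, homozygous
#' duplication).
#'
#' @param dq Numeric vector of DQ values (>= 0).
#' @param thresholds A [dq_thresholds()] object.
#' @return Character vector of categories (see `PROBE_CATEGORIES`).
#' @examples
#' th <- dq_thresholds()
#' classify_probe(c(1.00, 1.46, 2.81, 1.25), th)
#' @export
classify_probe <- function(dq, thresholds = dq_thresholds()) {
  th <- thresholds
  if (!is.numeric(dq) || any(!is.finite(dq)))
    fail("dq must be finite numeric")
  if (any(dq < 0)) fail("dq must be non-negative")
  out <- rep("borderline", length(dq))
  out[dq < th$homdel_max] <- "homozygous_deletion"
  out[dq >= th$hetdel_lo & dq <= th$hetdel_hi] <- "heterozygous_deletion"
  out[dq >= th$normal_lo & dq <= th$normal_hi] <- "normal"
  out[dq >= th$hetdup_lo & dq <= th$hetdup_hi] <- "heterozygous_duplication"
  out[dq >= th$homdup_lo & dq <= th$homdup_hi] <- "homozygous_duplication"
  out[dq > th$homdup_hi] <- "amplification"
  out
}

# DQ vector for one sample in chromosomal probe order, validated vs panel.
ordered_target_dq <- function(dq, panel) {
  if (is.matrix(dq)) {
    if (ncol(dq) != 1L) fail("expected a single-sample DQ profile")
    dq <- stats::setNames(dq[, 1L], rownames(dq))
  }
  if (is.null(names(dq))) fail("DQ profile must be named by probe_id")
  tgt <- target_probes(panel)
  missing <- setdiff(tgt$probe_id, names(dq))
  if (length(missing))
    fail("DQ profile lacks probe(s): %s", paste(missing, collapse = ", "))
  if (any(!is.finite(dq)) || any(dq < 0))
    fail("DQ values must be finite and non-negative")
  stats::setNames(dq[tgt$probe_id], tgt$probe_id)
}

#' Detect the amplified block of a DQ profile
#'
#' Finds the longest maximal run of order-consecutive chromosome-21 probes
#' with DQ at or above `gain_threshold` (ties broken by higher mean DQ).
#' This is the pattern that distinguishes iAMP21 — a megabase block of
#' amplification between non-amplified flanks — from whole-chromosome gain.
#'
#' @param dq Named DQ vector (or one-column matrix) for one sample.
#' @param panel Probe panel.
#' @param gain_threshold Minimum DQ for a probe to join the block
#'   (default 1.35, the heterozygous-duplication floor).
#' @param thresholds Thresholds used to classify the flanking probes.
#' @return `NULL` when no probe reaches `gain_threshold`; otherwise a list
#'   of class `amplified_block` with probe/gene endpoints, `n_probes`,
#'   `span_mbp` (from the panel's approximate coordinates),
#'   `contains_runx1`, `contains_erg`, `flanks_normal` (the probes
#'   immediately outside the block, where they exist, classify as normal),
#'   and `mean_dq`.
#' @export
detect_amplified_block <- function(dq, panel, gain_threshold = 1.35,
                                   thresholds = dq_thresholds()) {
  v <- ordered_target_dq(dq, panel)
  tgt <- target_probes(panel)
  gained <- v >= gain_threshold
  if (!any(gained)) return(NULL)
  r <- rle(gained)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs$len <- runs$end - runs$start + 1L
  runs$mean <- vapply(seq_len(nrow(runs)),
                      function(i) mean(v[runs$start[i]:runs$end[i]]), 0)
  best <- runs[order(-runs$len, -runs$mean), , drop = FALSE][1L, ]
  i0 <- best$start; i1 <- best$end
  genes_in <- tgt$gene_symbol[i0:i1]
  flank_idx <- c(if (i0 > 1L) i0 - 1L, if (i1 < nrow(tgt)) i1 + 1L)
  flanks_normal <- length(flank_idx) == 0L ||
    all(classify_probe(v[flank_idx], thresholds) == "normal")
  structure(list(
    start_probe_id = tgt$probe_id[i0], end_probe_id = tgt$probe_id[i1],
    start_gene = tgt$gene_symbol[i0], end_gene = tgt$gene_symbol[i1],
    n_probes = best$len,
    span_mbp = tgt$approx_start_mbp[i1] - tgt$approx_start_mbp[i0],
    contains_runx1 = any(tgt$is_runx1[i0:i1]),
    contains_erg = "ERG" %in% genes_in,
    flanks_normal = flanks_normal,
    mean_dq = best$mean), class = "amplified_block")
}

#' Is a profile uniformly elevated?
#'
#' Whole-chromosome gain (e.g. hyperdiploidy with extra chromosomes 21)
#' raises every probe by a similar factor, unlike the focal iAMP21 block.
#' A profile counts as uniformly elevated when at least
#' `uniform_gain_fraction` of target probes classify into a gain category
#' and the profile is flat: the ratio of the 90th to the 10th DQ percentile
#' stays below `uniform_percentile_ratio`.
#'
#' @param dq Named DQ vector for one sample.
#' @param panel Probe panel.
#' @param thresholds A [dq_thresholds()] object (carries the uniformity
#'   parameters).
#' @return Logical scalar.
#' @export
is_uniform_elevation <- function(dq, panel, thresholds = dq_thresholds()) {
  v <- ordered_target_dq(dq, panel)
  gain_frac <- mean(classify_probe(v, thresholds) %in% GAIN_CATEGORIES)
  q <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  flat <- q[1L] > 0 && (q[2L] / q[1L]) < thresholds$uniform_percentile_ratio
  gain_frac >= thresholds$uniform_gain_fraction && flat
}

#' Sample-level diagnostic call
#'
#' Applies the diagnostic decision ladder to one DQ profile:
#' \enumerate{
#'   \item median RUNX1 DQ above the iAMP21 threshold and the profile is
#'     not uniformly elevated: `iamp21`;
#'   \item median RUNX1 DQ above the threshold but uniformly elevated:
#'     `chr21_multiplication` with a hyperdiploidy note (whole-chromosome
#'     gain can push RUNX1 past the threshold without focal amplification);
#'   \item median DQ of all probes at or above the duplication floor:
#'     `chr21_multiplication`;
#'   \item median DQ of all probes inside the normal window:
#'     `no_chr21_aberration`;
#'   \item otherwise `indeterminate`.
#' }
#' Balanced ETV6-RUNX1 fusions are copy-neutral and therefore (correctly)
#' call `no_chr21_aberration`: dosage analysis cannot see them.
#'
#' @param dq Named DQ vector (or one-column matrix) for one sample.
#' @param panel Probe panel.
#' @param thresholds A [dq_thresholds()] object.
#' @param sample_id Sample identifier carried into the call.
#' @return List of class `sample_call`: `sample_id`, `category`,
#'   `median_dq_all`, `median_dq_runx1`, `block` (an `amplified_block` or
#'   `NULL`), `uniform_elevation`, `notes` (character vector).
#' @export
classify_sample <- function(dq, panel, thresholds = dq_thresholds(),
                            sample_id = "sample") {
  v <- ordered_target_dq(dq, panel)
  th <- thresholds
  med_all <- stats::median(v)
  med_runx1 <- stats::median(v[runx1_probe_ids(panel)])
  uniform <- is_uniform_elevation(v, panel, th)
  block <- detect_amplified_block(v, panel, gain_threshold = th$hetdup_lo,
                                  thresholds = th)
  notes <- character()
  if (med_runx1 > th$iamp21_runx1 && !uniform) {
    category <- "iamp21"
    if (!is.null(block))
      notes <- c(notes, sprintf("amplified block %s..%s (%d probes, %.2f Mbp)",
                                block$start_gene, block$end_gene,
                                block$n_probes, block$span_mbp))
  } else if (med_runx1 > th$iamp21_runx1 && uniform) {
    category <- "chr21_multiplication"
    notes <- c(notes,
               "uniform elevation: hyperdiploidy suspected, iAMP21 criteria not met")
  } else if (med_all >= th$hetdup_lo) {
    category <- "chr21_multiplication"
  } else if (med_all >= th$normal_lo && med_all <= th$normal_hi) {
    category <- "no_chr21_aberration"
  } else {
    category <- "indeterminate"
    notes <- c(notes, sprintf(
      "median DQ %.3f falls outside both the normal window [%.2f, %.2f] and the duplication range (>= %.2f)",
      med_all, th$normal_lo, th$normal_hi, th$hetdup_lo))
  }
  structure(list(sample_id = sample_id, category = category,
                 median_dq_all = unname(med_all),
                 median_dq_runx1 = unname(med_runx1),
                 block = block, uniform_elevation = uniform, notes = notes),
            class = "sample_call")
}

#' Call every sample of a DQ matrix
#'
#' @param dq DQ matrix (target probes by samples) from [compute_dq()].
#' @param panel Probe panel.
#' @param thresholds A [dq_thresholds()] object.
#' @return Data frame of class `mlpa_calls`, one row per sample, with
#'   columns `sample_id`, `category`, `median_dq_all`, `median_dq_runx1`,
#'   `block_start_gene`, `block_end_gene`, `block_n_probes`,
#'   `block_span_mbp`, `uniform_elevation`, `notes` (semicolon-joined).
#' @export
classify_cohort <- function(dq, panel, thresholds = dq_thresholds()) {
  if (!is.matrix(dq)) fail("dq must be a probes-x-samples matrix")
  if (is.null(colnames(dq))) fail("dq matrix must have sample_id colnames")
  calls <- lapply(colnames(dq), function(s)
    classify_sample(dq[, s], panel, thresholds, sample_id = s))
  df <- data.frame(
    sample_id = vapply(calls, `[[`, "", "sample_id"),
    category = vapply(calls, `[[`, "", "category"),
    median_dq_all = vapply(calls, `[[`, 0, "median_dq_all"),
    median_dq_runx1 = vapply(calls, `[[`, 0, "median_dq_runx1"),
    block_start_gene = vapply(calls, function(x)
      x$block$start_gene %||% NA_character_, ""),
    block_end_gene = vapply(calls, function(x)
      x$block$end_gene %||% NA_character_, ""),
    block_n_probes = vapply(calls, function(x)
      as.integer(x$block$n_probes %||% NA_integer_), 1L),
    block_span_mbp = vapply(calls, function(x)
      as.numeric(x$block$span_mbp %||% NA_real_), 0),
    uniform_elevation = vapply(calls, `[[`, TRUE, "uniform_elevation"),
    notes = vapply(calls, function(x) paste(x$notes, collapse = "; "), ""),
    stringsAsFactors = FALSE)
  structure(df, class = c("mlpa_calls", "data.frame"))
}

#' @export
print.sample_call <- function(x, ...) {
  cat(sprintf("%s: %s (median DQ all %.2f, RUNX1 %.2f%s)\n", x$sample_id,
              x$category, x$median_dq_all, x$median_dq_runx1,
              if (x$uniform_elevation) ", uniformly elevated" else ""))
  if (!is.null(x$block))
    cat(sprintf("  block: %s..%s, %d probes, %.2f Mbp, RUNX1 %s, ERG %s, normal flanks %s\n",
                x$block$start_gene, x$block$end_gene, x$block$n_probes,
                x$block$span_mbp, x$block$contains_runx1,
                x$block$contains_erg, x$block$flanks_normal))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
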