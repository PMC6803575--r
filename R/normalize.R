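# Two-stage Dosage Quotient normalization.
#
# Stage 1 (intra-sample): each probe peak is divided by the median peak of
# the reference probes of the same sample, removing per-sample differences in
# DNA input and overall PCR yield.
# Stage 2 (inter-sample): the relative ratio is divided by the average
# relative ratio of the same probe across healthy reference samples, removing
# per-probe amplification efficiency. The result is the Dosage Quotient (DQ),
# ~1.0 for a diploid locus.

# Coerce a single run (named vector) or a cohort (matrix / data.frame with
# probe rows and sample columns) to a probes-x-samples numeric matrix.
as_peak_matrix <- function(peaks, panel, what = "peaks") {
  if (is.numeric(peaks) && !is.matrix(peaks)) {
    if (is.null(names(peaks)))
      fail("%s vector must be named by probe_id", what)
    peaks <- matrix(peaks, ncol = 1L,
                    dimnames = list(names(peaks), "sample_1"))
  }
  if (is.data.frame(peaks)) peaks <- as.matrix(peaks)
  if (!is.matrix(peaks) || !is.numeric(peaks))
    fail("%s must be a named numeric vector or a probes-x-samples matrix", what)
  if (is.null(rownames(peaks))) fail("%s matrix must have probe_id rownames", what)
  dup <- rownames(peaks)[duplicated(rownames(peaks))]
  if (length(dup))
    fail("%s: duplicated probe row(s): %s", what, paste(unique(dup), collapse = ", "))
  missing <- setdiff(panel$probe_id, rownames(peaks))
  if (length(missing))
    fail("%s: missing probe(s) required by panel: %s", what,
         paste(missing, collapse = ", "))
  if (any(!is.finite(peaks)) || any(peaks < 0))
    fail("%s must be finite and non-negative", what)
  peaks[panel$probe_id, , drop = FALSE]
}

#' Intra-sample normalization of raw MLPA peaks
#'
#' Divides every probe peak by the median reference-probe peak of the same
#' sample, yielding relative probe ratios. The output is scale-free:
#' multiplying all peaks of a sample by any positive constant leaves it
#' unchanged.
#'
#' @param peaks Raw peak fluorescence: a named numeric vector (one run) or a
#'   probes-by-samples matrix with `probe_id` rownames. Every panel probe
#'   must be present.
#' @param panel An [load_panel()] probe panel.
#' @return Matrix of relative ratios, same shape as the input (vectors are
#'   returned as one-column matrices).
#' @examples
#' panel <- load_panel("P327")
#' run <- setNames(rep(1000, nrow(panel)), panel$probe_id)
#' rel <- intra_sample_normalize(run, panel)
#' all(rel == 1)
#' @export
intra_sample_normalize <- function(peaks, panel) {
  m <- as_peak_matrix(peaks, panel)
  ref <- reference_probe_ids(panel)
  if (length(ref) == 0L) fail("panel has no reference probes")
  ref_med <- apply(m[ref, , drop = FALSE], 2L, stats::median)
  bad <- colnames(m)[ref_med <= 0]
  if (length(bad))
    fail("normalization error: reference peaks are all zero (or median zero) in sample(s): %s",
         paste(bad, collapse = ", "))
  sweep(m, 2L, ref_med, "/")
}

#' Build a healthy-reference set
#'
#' Normalizes each healthy run intra-sample and averages the relative ratio
#' of every probe across runs (arithmetic mean). At least three reference
#' runs are required so that the average is meaningful and no single run
#' dominates.
#'
#' @param peaks Raw peaks of the healthy runs, probes-by-samples matrix
#'   (>= 3 columns).
#' @param panel Probe panel.
#' @return An object of class `mlpa_reference_set` with elements
#'   `per_probe_mean` (named vector), `n_profiles` and `panel_name`.
#' @export
build_reference_set <- function(peaks, panel) {
  m <- as_peak_matrix(peaks, panel, what = "reference peaks")
  if (ncol(m) < 3L)
    fail("insufficient reference runs: %d supplied, at least 3 required", ncol(m))
  rel <- intra_sample_normalize(m, panel)
  mu <- rowMeans(rel)
  tgt <- target_probes(panel)$probe_id
  zero <- tgt[mu[tgt] <= 0]
  if (length(zero))
    fail("reference set has non-positive mean ratio at probe(s): %s",
         paste(zero, collapse = ", "))
  structure(list(per_probe_mean = mu, n_profiles = ncol(m),
                 panel_name = attr(panel, "name") %||% "panel"),
            class = "mlpa_reference_set")
}

#' Compute Dosage Quotients
#'
#' Divides each sample's relative probe ratio by the reference-set mean for
#' the same probe. Only chromosome-21 target probes are reported; reference
#' probes exist solely to support the intra-sample stage. A zero target peak
#' yields DQ 0 (homozygous-deletion semantics), not an error.
#'
#' @param relative Output of [intra_sample_normalize()] (vector or matrix).
#' @param ref An `mlpa_reference_set` from [build_reference_set()].
#' @param panel Probe panel shared by both.
#' @return Numeric matrix of DQ values, target probes (chromosomal order) by
#'   samples.
#' @export
compute_dq <- function(relative, ref, panel) {
  if (!inherits(ref, "mlpa_reference_set"))
    fail("ref must be built with build_reference_set()")
  m <- as_peak_matrix(relative, panel, what = "relative ratios")
  tgt <- target_probes(panel)$probe_id
  mu <- ref$per_probe_mean[tgt]
  if (anyNA(mu))
    fail("reference set lacks probe(s): %s",
         paste(tgt[is.na(mu)], collapse = ", "))
  zero <- tgt[mu == 0]
  if (length(zero))
    fail("reference mean is zero at probe(s): %s", paste(zero, collapse = ", "))
  sweep(m[tgt, , drop = FALSE], 1L, mu, "/")
}

#' Raw peaks to DQ in one step
#'
#' Convenience wrapper: intra-sample normalization of samples and reference
#' runs, reference-set construction, and DQ computation.
#'
#' @param peaks Raw peaks of the test samples (vector or matrix).
#' @param ref_peaks Raw peaks of >= 3 healthy reference runs.
#' @param panel Probe panel.
#' @return DQ matrix as from [compute_dq()].
#' @export
peaks_to_dq <- function(peaks, ref_peaks, panel) {
  ref <- build_reference_set(ref_peaks, panel)
  compute_dq(intra_sample_normalize(peaks, panel), ref, panel)
}

# Resolve a subset spec to probe ids; errors on unknown probes/empty subset.
resolve_subset <- function(subset, panel) {
  tgt <- target_probes(panel)$probe_id
  ids <- if (identical(subset, "all")) tgt
         else if (identical(subset, "runx1")) runx1_probe_ids(panel)
         else as.character(subset)
  unknown <- setdiff(ids, tgt)
  if (length(unknown))
    fail("subset names unknown target probe(s): %s",
         paste(unknown, collapse = ", "))
  if (length(ids) == 0L) fail("probe subset is empty")
  ids
}

#' Median DQ over a probe subset
#'
#' The per-sample summary statistic of the caller: the median DQ over all
#' chromosome-21 probes, over the six RUNX1 probes, or over an explicit
#' probe list. Even-sized subsets use the mean of the two central values.
#'
#' @param dq DQ matrix (or named vector for one sample) from [compute_dq()].
#' @param panel Probe panel.
#' @param subset `"all"`, `"runx1"`, or a character vector of probe ids.
#' @return Named numeric vector, one median per sample.
#' @export
median_dq <- function(dq, panel, subset = "all") {
  if (is.numeric(dq) && !is.matrix(dq))
    dq <- matrix(dq, ncol = 1L, dimnames = list(names(dq), "sample_1"))
  ids <- resolve_subset(subset, panel)
  missing <- setdiff(ids, rownames(dq))
  if (length(missing))
    fail("DQ profile lacks probe(s): %s", paste(missing, collapse = ", "))
  apply(dq[ids, , drop = FALSE], 2L, stats::median)
}

#' @export
print.mlpa_reference_set <- function(x, ...) {
  cat(sprintf("MLPA reference set: %d healthy profiles on panel '%s'\n",
              x$n_profiles, x$panel_name))
  cat(sprintf("  per-probe mean relative ratio over %d probes (range %.3f-%.3f)\n",
              length(x$per_probe_mean), min(x$per_probe_mean),
              max(x$per_probe_mean)))
  invisible(x)
}
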