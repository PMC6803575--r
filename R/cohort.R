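# Cohort-level statistics: group composition, per-group DQ summaries,
# nonparametric comparisons, and concordance against FISH/karyotype truth.

TRUTH_GROUPS <- c("none", "chr21_multiplication", "etv6_runx1", "iamp21")

# The sample call each truth group should produce in a dosage assay.
# Balanced ETV6-RUNX1 fusions are copy-neutral, hence expected to look normal.
EXPECTED_CALL <- c(none = "no_chr21_aberration",
                   chr21_multiplication = "chr21_multiplication",
                   etv6_runx1 = "no_chr21_aberration",
                   iamp21 = "iamp21")

#' Group composition percentages
#'
#' Converts per-group sample counts into percentages of either the whole
#' cohort or of the aberrant subset (all groups except `none`), reported to
#' two decimals with half-up rounding, the convention of clinical tables.
#'
#' @param counts Named non-negative integer vector of per-group counts.
#' @param denominator `"cohort"` (sum of all counts) or `"aberrant"` (sum
#'   excluding the group named `none`; the `none` entry is dropped from the
#'   output).
#' @return Named numeric vector of percentages.
#' @examples
#' counts <- c(chr21_multiplication = 56, etv6_runx1 = 34, iamp21 = 3, none = 142)
#' group_percentages(counts, "cohort")["none"]                 # 60.43
#' group_percentages(counts, "aberrant")["chr21_multiplication"] # 60.22
#' @export
group_percentages <- function(counts, denominator = c("cohort", "aberrant")) {
  denominator <- match.arg(denominator)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    fail("counts must be a named vector")
  if (any(!is.finite(counts)) || any(counts < 0))
    fail("counts must be non-negative numbers")
  if (denominator == "aberrant")
    counts <- counts[setdiff(names(counts), "none")]
  total <- sum(counts)
  if (total <= 0) fail("denominator resolves to zero samples")
  round_half_up(100 * counts / total, 2)
}

#' Per-group median and IQR of sample-level median DQ
#'
#' Summarizes each truth group by the median and interquartile range
#' (quartiles by linear interpolation, quantile type 7) of the per-sample
#' median DQ over a probe subset.
#'
#' @param dq DQ matrix (target probes by samples).
#' @param panel Probe panel.
#' @param truth Truth-label data frame with `sample_id` and `group`.
#' @param subset `"all"`, `"runx1"`, or a probe-id vector (see
#'   [median_dq()]).
#' @return Data frame with columns `group`, `n`, `median`, `iqr_lo`,
#'   `iqr_hi`; empty groups carry `n = 0` and `NA` statistics.
#' @export
group_medians <- function(dq, panel, truth, subset = "all") {
  check_truth(truth)
  missing <- setdiff(colnames(dq), truth$sample_id)
  if (length(missing))
    fail("samples lack truth labels: %s", paste(missing, collapse = ", "))
  med <- median_dq(dq, panel, subset)
  grp <- truth$group[match(colnames(dq), truth$sample_id)]
  rows <- lapply(TRUTH_GROUPS, function(g) {
    v <- med[grp == g]
    if (length(v) == 0L)
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        iqr_lo = NA_real_, iqr_hi = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(group = g, n = length(v), median = q[2L],
               iqr_lo = q[1L], iqr_hi = q[3L])
  })
  do.call(rbind, rows)
}

# Mann-Whitney U with midranks. Exact two-sided p by permutation enumeration
# (valid with ties, unlike the exact path of stats::wilcox.test) when the
# number of group assignments is small; normal approximation with tie
# correction otherwise.
mw_test <- function(x, y, max_enum = 100000) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (choose(n + m, n) <= max_enum) {
    idx <- utils::combn(n + m, n)
    us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(u = unname(u), p = unname(p))
}

#' Nonparametric group comparison
#'
#' Kruskal-Wallis omnibus test (tie-corrected) across all groups, followed
#' by pairwise two-sided Mann-Whitney U tests with Holm-adjusted p-values.
#' Pairwise p-values are exact (permutation enumeration, valid under ties)
#' for small groups and normal-approximated otherwise. Groups with fewer
#' than two values are excluded with a warning.
#'
#' @param values Named list mapping group name to a numeric vector.
#' @return List with `kw_statistic`, `kw_df`, `kw_p`, and `pairwise`, a data
#'   frame with columns `group1`, `group2`, `u_statistic`, `mw_p`,
#'   `mw_p_holm`.
#' @export
compare_groups <- function(values) {
  if (!is.list(values) || is.null(names(values)))
    fail("values must be a named list of numeric vectors")
  small <- names(values)[lengths(values) < 2L]
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 values: ",
            paste(small, collapse = ", "), call. = FALSE)
    values <- values[lengths(values) >= 2L]
  }
  if (length(values) < 2L)
    fail("at least 2 groups with >= 2 values are required")
  kw <- stats::kruskal.test(unname(values))
  pairs <- utils::combn(names(values), 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    t <- mw_test(values[[g1]], values[[g2]])
    data.frame(group1 = g1, group2 = g2, u_statistic = t$u, mw_p = t$p)
  })
  pw <- do.call(rbind, pw)
  pw$mw_p_holm <- stats::p.adjust(pw$mw_p, method = "holm")
  list(kw_statistic = unname(kw$statistic), kw_df = unname(kw$parameter),
       kw_p = unname(kw$p.value), pairwise = pw)
}

check_truth <- function(truth) {
  if (!is.data.frame(truth) || !all(c("sample_id", "group") %in% names(truth)))
    fail("truth must be a data frame with sample_id and group columns")
  bad <- setdiff(unique(truth$group), TRUTH_GROUPS)
  if (length(bad))
    fail("unknown truth group(s): %s (expected %s)",
         paste(bad, collapse = ", "), paste(TRUTH_GROUPS, collapse = ", "))
  dup <- truth$sample_id[duplicated(truth$sample_id)]
  if (length(dup))
    fail("duplicated truth sample_id(s): %s", paste(unique(dup), collapse = ", "))
  invisible(truth)
}

#' MLPA-vs-truth concordance report
#'
#' Cross-tabulates sample calls against FISH/karyotype truth and reports the
#' two error modes of a semi-quantitative dosage assay:
#' \itemize{
#'   \item false negatives among chromosome-21 gain samples — truth
#'     `chr21_multiplication` with median DQ (all probes) inside the normal
#'     window, the signature of blast-fraction dilution or subclonality;
#'   \item false positives among no-aberration samples — truth `none` called
#'     `chr21_multiplication` or with median DQ at or above the duplication
#'     floor;
#' }
#' plus iAMP21 sensitivity (detected / truth iAMP21).
#'
#' @param calls An `mlpa_calls` data frame from [classify_cohort()].
#' @param truth Truth-label data frame (`sample_id`, `group`).
#' @param thresholds A [dq_thresholds()] object.
#' @return List of class `concordance_report` with `n_samples`,
#'   `group_counts`, `confusion` (truth x call table), `fn_chr21_gain`
#'   (`count`, `rate_percent`), `fp_none` (`count`, `rate_percent`),
#'   `iamp21_sensitivity`, and `call_accuracy_percent` (fraction of samples
#'   whose call matches the call expected for their truth group, with
#'   copy-neutral ETV6-RUNX1 expected to call `no_chr21_aberration`).
#' @export
concordance <- function(calls, truth, thresholds = dq_thresholds()) {
  check_truth(truth)
  if (!is.data.frame(calls) || !"sample_id" %in% names(calls))
    fail("calls must be a data frame with a sample_id column")
  only_calls <- setdiff(calls$sample_id, truth$sample_id)
  only_truth <- setdiff(truth$sample_id, calls$sample_id)
  if (length(only_calls) || length(only_truth))
    fail("calls and truth cover different samples (calls-only: %s; truth-only: %s)",
         paste(only_calls, collapse = ",") %e% "none",
         paste(only_truth, collapse = ",") %e% "none")
  th <- thresholds
  m <- merge(calls, truth[c("sample_id", "group")], by = "sample_id")
  group_counts <- table(factor(m$group, levels = TRUTH_GROUPS))
  confusion <- table(truth = factor(m$group, levels = TRUTH_GROUPS),
                     call = m$category)

  gain <- m[m$group == "chr21_multiplication", , drop = FALSE]
  fn <- sum(gain$median_dq_all >= th$normal_lo &
              gain$median_dq_all <= th$normal_hi)
  none <- m[m$group == "none", , drop = FALSE]
  fp <- sum(none$category == "chr21_multiplication" |
              none$median_dq_all >= th$hetdup_lo)
  n_iamp <- sum(m$group == "iamp21")
  sens <- if (n_iamp > 0)
    sum(m$group == "iamp21" & m$category == "iamp21") / n_iamp
  else NA_real_
  accuracy <- mean(m$category == EXPECTED_CALL[m$group])

  rate <- function(k, n) if (n > 0) round_half_up(100 * k / n, 2) else NA_real_
  structure(list(
    n_samples = nrow(m),
    group_counts = group_counts,
    confusion = confusion,
    fn_chr21_gain = list(count = fn, rate_percent = rate(fn, nrow(gain))),
    fp_none = list(count = fp, rate_percent = rate(fp, nrow(none))),
    iamp21_sensitivity = sens,
    call_accuracy_percent = round_half_up(100 * accuracy, 2)),
    class = "concordance_report")
}

`%e%` <- function(a, b) if (nzchar(a)) a else b

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance over %d samples\n", x$n_samples))
  print(x$confusion)
  cat(sprintf("False negatives among chr21-gain: %d (%.2f%%)\n",
              x$fn_chr21_gain$count, x$fn_chr21_gain$rate_percent))
  cat(sprintf("False positives among no-aberration: %d (%.2f%%)\n",
              x$fp_none$count, x$fp_none$rate_percent))
  if (!is.na(x$iamp21_sensitivity))
    cat(sprintf("iAMP21 sensitivity: %.2f\n", x$iamp21_sensitivity))
  cat(sprintf("Expected-call accuracy: %.2f%%\n", x$call_accuracy_percent))
  invisible(x)
}
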