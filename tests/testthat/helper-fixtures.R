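# Shared fixtures and independent oracles for the test suite.

p327 <- load_panel("P327")

# A raw run with every panel probe at `value` (optionally overridden).
uniform_run <- function(panel = p327, value = 1000, overrides = NULL) {
  peaks <- stats::setNames(rep(value, nrow(panel)), panel$probe_id)
  if (!is.null(overrides)) peaks[names(overrides)] <- overrides
  peaks
}

# A DQ profile (named vector over target probes, chromosomal order) with a
# baseline value and per-gene or per-probe overrides.
flat_dq <- function(panel = p327, value = 1.0, gene_values = NULL) {
  tgt <- panel[!panel$is_reference, , drop = FALSE]
  tgt <- tgt[order(tgt$order_index), ]
  v <- stats::setNames(rep(value, nrow(tgt)), tgt$probe_id)
  for (g in names(gene_values)) v[tgt$probe_id[tgt$gene_symbol == g]] <- gene_values[[g]]
  v
}

# DQ profile mimicking an iAMP21 case: the NCAM2..RIPK4 interval elevated,
# diploid flanks.
iamp21_dq <- function(panel = p327, block_value = 2.8, flank_value = 1.0) {
  blk <- probes_in_region(panel, "NCAM2", "RIPK4")$probe_id
  v <- flat_dq(panel, flank_value)
  v[blk] <- block_value
  v
}

# Independent brute-force oracle for amplified-block detection: enumerate
# every contiguous window, keep those fully at/above the threshold, pick the
# longest (ties by higher mean DQ).
brute_force_block <- function(dq_ordered, threshold = 1.35) {
  k <- length(dq_ordered)
  best <- NULL
  for (i in seq_len(k)) for (j in i:k) {
    w <- dq_ordered[i:j]
    if (all(w >= threshold)) {
      cand <- list(start = i, end = j, len = j - i + 1L, mean = mean(w))
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && cand$mean > best$mean)) best <- cand
    }
  }
  best
}

# Closed-form Kruskal-Wallis H with tie correction, computed from first
# principles (independent of stats::kruskal.test).
kw_closed_form <- function(values) {
  x <- unlist(values, use.names = FALSE)
  g <- rep(seq_along(values), lengths(values))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Severity rank of non-borderline probe categories, for monotonicity checks.
category_rank <- c(homozygous_deletion = 1, heterozygous_deletion = 2,
                   normal = 3, heterozygous_duplication = 4,
                   homozygous_duplication = 5, amplification = 6)
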