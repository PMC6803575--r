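# Probe panel: the ordered catalogue of MLPA probes every profile lives on.

#' Load an MLPA probe panel
#'
#' Reads a probe panel from a tab-delimited catalogue file, or returns the
#' packaged reconstruction of the P327 iAMP21-ERG probemix when given the
#' builtin name `"P327"`. The packaged panel carries 46 chromosome-21 target
#' probes in centromere-to-telomere order (6 of them on RUNX1) plus 8
#' off-chromosome reference probes used only for intra-sample normalization.
#' Coordinates in the packaged panel are approximate and synthetic; they are
#' used only for probe ordering and block-span reporting.
#'
#' @param path_or_builtin Path to a panel TSV, or `"P327"` for the packaged
#'   panel. The TSV has columns `probe_id`, `gene_symbol`, `cytoband`,
#'   `order_index`, `approx_start_mbp`, `is_runx1`, `is_reference`;
#'   `#`-prefixed header lines are ignored.
#' @return A data frame of class `mlpa_panel`, one row per probe, ordered by
#'   `order_index` with reference probes (which have `NA` order) last.
#' @seealso [probes_in_region()], [write_panel()]
#' @examples
#' panel <- load_panel("P327")
#' sum(!panel$is_reference)        # 46 chromosome-21 probes
#' sum(panel$is_runx1)             # 6 RUNX1 probes
#' @export
load_panel <- function(path_or_builtin = "P327") {
  path <- path_or_builtin
  if (identical(path, "P327")) {
    path <- system.file("extdata", "p327_panel_synthetic.tsv",
                        package = "mlpa21", mustWork = TRUE)
  }
  if (!file.exists(path)) fail("panel file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      na.strings = "NA"),
    error = function(e) fail("malformed panel TSV '%s': %s", path,
                             conditionMessage(e)))
  required <- c("probe_id", "gene_symbol", "cytoband", "order_index",
                "approx_start_mbp", "is_runx1", "is_reference")
  missing <- setdiff(required, names(df))
  if (length(missing))
    fail("panel '%s' lacks required column(s): %s", path,
         paste(missing, collapse = ", "))
  df <- df[required]
  df$order_index <- as.integer(df$order_index)
  df$approx_start_mbp <- as.numeric(df$approx_start_mbp)
  df$is_runx1 <- as.logical(df$is_runx1)
  df$is_reference <- as.logical(df$is_reference)
  panel <- new_panel(df, name = basename(path))
  if (identical(path_or_builtin, "P327")) attr(panel, "name") <- "P327"
  validate_panel(panel)
  panel
}

new_panel <- function(df, name = "panel", version = "1") {
  ord <- order(df$is_reference, df$order_index)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("mlpa_panel", "data.frame"),
            name = name, version = version)
}

# Enforce the panel invariants: unique ids, contiguous 0-based order among
# target probes, order consistent with coordinates, sentinel NA order for
# reference probes.
validate_panel <- function(panel) {
  dup <- panel$probe_id[duplicated(panel$probe_id)]
  if (length(dup))
    fail("panel validation: duplicate probe_id(s): %s",
         paste(unique(dup), collapse = ", "))
  tgt <- panel[!panel$is_reference, , drop = FALSE]
  if (nrow(tgt) == 0L) fail("panel validation: no target probes")
  if (anyNA(tgt$order_index))
    fail("panel validation: target probes must have an order_index")
  if (!identical(sort(tgt$order_index), seq_len(nrow(tgt)) - 1L))
    fail("panel validation: order_index must be unique and contiguous 0..%d",
         nrow(tgt) - 1L)
  o <- order(tgt$order_index)
  if (is.unsorted(tgt$approx_start_mbp[o]))
    fail("panel validation: order_index disagrees with approx_start_mbp")
  ref <- panel[panel$is_reference, , drop = FALSE]
  if (!all(is.na(ref$order_index)))
    fail("panel validation: reference probes must have NA order_index")
  if (any(ref$is_runx1))
    fail("panel validation: a reference probe cannot target RUNX1")
  invisible(panel)
}

#' Write a probe panel to TSV
#'
#' @param panel An `mlpa_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mlpa21 probe panel\t name=%s\tversion=%s",
                     attr(panel, "name") %||% "panel",
                     attr(panel, "version") %||% "1"), con)
  out <- as.data.frame(panel)
  out$approx_start_mbp <- ifelse(is.na(out$approx_start_mbp), "NA",
                                 sprintf("%.2f", out$approx_start_mbp))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Target (chromosome-21) probes in chromosomal order.
target_probes <- function(panel) {
  tgt <- panel[!panel$is_reference, , drop = FALSE]
  tgt[order(tgt$order_index), , drop = FALSE]
}

reference_probe_ids <- function(panel) panel$probe_id[panel$is_reference]

runx1_probe_ids <- function(panel) panel$probe_id[panel$is_runx1]

#' Target probes between two genes
#'
#' Returns the chromosome-21 probes whose position lies between the first
#' probe of `from_gene` and the last probe of `to_gene`, inclusive on both
#' ends. Used, e.g., to select the NCAM2..RIPK4 interval that carries the
#' recurrent iAMP21 amplification block.
#'
#' @param panel An `mlpa_panel`.
#' @param from_gene,to_gene Gene symbols present in the panel.
#' @return Data frame of target probes in chromosomal order.
#' @examples
#' panel <- load_panel("P327")
#' blk <- probes_in_region(panel, "NCAM2", "RIPK4")
#' any(blk$is_runx1)      # RUNX1 lies inside the interval
#' @export
probes_in_region <- function(panel, from_gene, to_gene) {
  tgt <- target_probes(panel)
  for (g in unique(c(from_gene, to_gene)))
    if (!g %in% tgt$gene_symbol)
      fail("gene '%s' not present among panel target probes", g)
  lo <- min(tgt$order_index[tgt$gene_symbol == from_gene])
  hi <- max(tgt$order_index[tgt$gene_symbol == to_gene])
  if (lo > hi)
    fail("'%s' lies after '%s' on the chromosome", from_gene, to_gene)
  tgt[tgt$order_index >= lo & tgt$order_index <= hi, , drop = FALSE]
}

#' @export
print.mlpa_panel <- function(x, ...) {
  tgt <- x[!x$is_reference, , drop = FALSE]
  cat(sprintf("MLPA probe panel '%s' (version %s)\n",
              attr(x, "name") %||% "panel", attr(x, "version") %||% "1"))
  cat(sprintf("  %d chromosome-21 target probes (%d RUNX1), %d reference probes\n",
              nrow(tgt), sum(x$is_runx1), sum(x$is_reference)))
  cat(sprintf("  span: %s (%.2f Mbp) .. %s (%.2f Mbp)\n",
              tgt$gene_symbol[which.min(tgt$order_index)],
              min(tgt$approx_start_mbp, na.rm = TRUE),
              tgt$gene_symbol[which.max(tgt$order_index)],
              max(tgt$approx_start_mbp, na.rm = TRUE)))
  invisible(x)
}
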