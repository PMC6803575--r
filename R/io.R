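# Flat-file round-tripping: peak tables, DQ tables, calls, truth labels,
# configuration. All tables are UTF-8, tab-separated, Unix newlines, '.'
# decimal point; matrix tables carry a versioned '#'-header so that readers
# can refuse files written by an incompatible writer.

PEAKS_HEADER <- "#mlpa-peaks v1"
DQ_HEADER <- "#dq-table v1"

write_versioned_matrix <- function(m, path, header) {
  if (!is.matrix(m)) fail("expected a matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df <- data.frame(probe_id = rownames(m),
                   signif(m, 6), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_versioned_matrix <- function(path, header, what) {
  if (!file.exists(path)) fail("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!identical(first, header))
    fail("%s '%s': expected header '%s', found '%s'", what, path, header,
         if (length(first)) first else "<empty file>")
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(df))
    fail("%s '%s': missing probe_id column", what, path)
  samples <- names(df)[names(df) != "probe_id"]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    fail("%s '%s': duplicated sample column(s): %s", what, path,
         paste(unique(dup), collapse = ", "))
  if (length(samples) == 0L) fail("%s '%s': no sample columns", what, path)
  if (nrow(df) == 0L) fail("%s '%s': no probe rows", what, path)
  m <- as.matrix(df[samples])
  if (!is.numeric(m)) fail("%s '%s': non-numeric values", what, path)
  rownames(m) <- df$probe_id
  m
}

#' Read / write raw peak tables
#'
#' Tab-delimited, first column `probe_id`, one column per sample, values
#' raw peak fluorescence; first line `#mlpa-peaks v1`.
#'
#' @param path File path.
#' @return `read_peak_table`: numeric matrix, probes by samples.
#' @export
read_peak_table <- function(path)
  read_versioned_matrix(path, PEAKS_HEADER, "peak table")

#' @rdname read_peak_table
#' @param peaks Probes-by-samples matrix.
#' @export
write_peak_table <- function(peaks, path)
  write_versioned_matrix(peaks, path, PEAKS_HEADER)

#' Read / write DQ tables
#'
#' Same shape as peak tables with header line `#dq-table v1`; values are
#' written at 6 significant digits, which bounds the round-trip error
#' below 1e-6 on the DQ scale.
#'
#' @param path File path.
#' @return `read_dq_table`: numeric matrix, target probes by samples.
#' @export
read_dq_table <- function(path)
  read_versioned_matrix(path, DQ_HEADER, "DQ table")

#' @rdname read_dq_table
#' @param dq Target-probes-by-samples DQ matrix.
#' @export
write_dq_table <- function(dq, path)
  write_versioned_matrix(dq, path, DQ_HEADER)

#' Read / write truth labels
#'
#' Tab-delimited truth table with columns `sample_id`, `group` and optional
#' `extra_chr21_copies`, `hyperdiploid`, `blast_percent`,
#' `mrd_day15_percent`.
#'
#' @param path File path.
#' @return `read_truth`: validated data frame.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_truth(df)
  df
}

#' @rdname read_truth
#' @param truth Truth data frame.
#' @export
write_truth <- function(truth, path) {
  check_truth(truth)
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample-call tables
#'
#' @param path File path.
#' @return `read_calls`: `mlpa_calls` data frame.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "category", "median_dq_all", "median_dq_runx1")
  missing <- setdiff(need, names(df))
  if (length(missing))
    fail("calls table '%s' lacks column(s): %s", path,
         paste(missing, collapse = ", "))
  structure(df, class = c("mlpa_calls", "data.frame"))
}

#' @rdname read_calls
#' @param calls `mlpa_calls` data frame.
#' @export
write_calls <- function(calls, path) {
  out <- as.data.frame(calls)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], signif, 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a pipeline configuration
#'
#' JSON configuration with optional blocks `thresholds` (overrides for
#' [dq_thresholds()]) and `simulation` (overrides for [sim_config()]).
#' Unknown keys anywhere are rejected so that typos cannot silently fall
#' back to defaults.
#'
#' @param path Path to a JSON file.
#' @return List with elements `thresholds` (a `dq_thresholds` object) and
#'   `simulation` (argument overrides for [sim_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), c("thresholds", "simulation"))
  if (length(unknown))
    fail("config '%s': unknown top-level key(s): %s", path,
         paste(unknown, collapse = ", "))
  th_over <- as.list(cfg$thresholds %||% list())
  bad <- setdiff(names(th_over), names(formals(dq_thresholds)))
  if (length(bad))
    fail("config '%s': unknown thresholds key(s): %s", path,
         paste(bad, collapse = ", "))
  sim_over <- as.list(cfg$simulation %||% list())
  bad <- setdiff(names(sim_over), names(formals(sim_config)))
  if (length(bad))
    fail("config '%s': unknown simulation key(s): %s", path,
         paste(bad, collapse = ", "))
  list(thresholds = do.call(dq_thresholds, th_over), simulation = sim_over)
}

# Serialize a concordance report (and friends) to JSON.
report_to_json <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, "table")) {
      as.list(stats::setNames(as.vector(x), names(x) %||%
                                apply(expand.grid(dimnames(x)), 1L, paste,
                                      collapse = ":")))
    } else if (is.list(x)) lapply(x, to_plain)
    else x
  }
  jsonlite::write_json(to_plain(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
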