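# Delimited-text input/output. Datasets travel as CSV with one row per
# subject and empty cells for missing values; metrics tables as CSV with a
# documented header (see run_grid()).

#' Write or read a simulated dataset as CSV
#'
#' Missing wave-2 measurements are written as empty cells. Reading
#' restores the canonical factor levels, so a round-trip reproduces the
#' table.
#'
#' @param data Dataset (any pipeline stage).
#' @param path File path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   the restored data.frame.
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  for (var in names(COHORT_LEVELS)) {
    if (var %in% names(d))
      d[[var]] <- factor(d[[var]], levels = COHORT_LEVELS[[var]])
  }
  if ("censor_cause" %in% names(d))
    d$censor_cause[d$censor_cause == ""] <- NA_character_
  d
}
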