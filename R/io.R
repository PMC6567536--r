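#' Read and write simulated samples as CSV
#'
#' Samples serialize to plain CSV with deterministic column order
#' (`x1, x2, x3, y_cont` plus, for observed samples, `m` and `y_obs`;
#' a `y_cat` column is kept when present).  Missing outcome entries
#' are written as empty fields.
#'
#' @param sample A `complete_sample` or `observed_sample` data frame.
#' @param path File path.
#' @return `write_sample_csv()` returns `path` invisibly;
#'   `read_sample_csv()` returns a data frame.
#' @export
write_sample_csv <- function(sample, path) {
  cols <- intersect(c("x1", "x2", "x3", "y_cont", "m", "y_obs", "y_cat"),
                    names(sample))
  utils::write.csv(as.data.frame(sample)[cols], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sample_csv
#' @export
read_sample_csv <- function(path) {
  utils::read.csv(path, na.strings = "")
}
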