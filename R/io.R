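#' Read discrete survival data from delimited text
#'
#' The outcome file must contain columns `time` and `status` (any extra
#' columns are ignored); the covariate file holds one subject per row
#' with a header row of feature identifiers. Field separators are
#' auto-detected from the extension (`.csv` = comma, otherwise tab)
#' unless given explicitly.
#'
#' @param outcome_file Path to the outcome table.
#' @param covariate_file Path to the covariate matrix.
#' @param sep Field separator; `NULL` to auto-detect per file.
#' @param n_intervals Total number of intervals; default `max(time)`.
#' @return A [discrete_survival_data] object.
#' @export
read_survival_data <- function(outcome_file, covariate_file, sep = NULL,
                               n_intervals = NULL) {
  out <- read_delim_auto(outcome_file, sep)
  if (!all(c("time", "status") %in% names(out))) {
    stop("Outcome file must have `time` and `status` columns.", call. = FALSE)
  }
  x <- as.matrix(read_delim_auto(covariate_file, sep))
  discrete_survival_data(out$time, out$status, x, n_intervals = n_intervals)
}

#' Write long-format Bernoulli records to delimited text
#'
#' @param long A tibble from [bernoulli_long()].
#' @param path Output path (`.csv` writes comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_bernoulli_long <- function(long, path) {
  stopifnot(all(c("subject", "interval", "y") %in% names(long)))
  write_delim_auto(as.data.frame(long), path)
  invisible(path)
}

read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_delim_auto <- function(df, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
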