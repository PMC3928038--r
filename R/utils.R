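## Shared internal helpers: seeded sub-streams, TSV I/O, small checks.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Each pipeline stage (genome, plants, genes, peaks, expression, ...) draws
#' its RNG state from a named sub-stream so stages can be regenerated
#' independently of each other. Kept strictly below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage stage name (character) or integer stage index.
#' @return an integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  ## products stay far below 2^53 so the arithmetic is exact in doubles
  as.integer((((as.numeric(seed) %% 1000003) * 10007) + stage * 101) %% 2147483647L)
}

#' Write a TSV report with a header row
#' @param df data.frame to write.
#' @param path output path.
#' @param comment optional character vector written as `#`-prefixed lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#' @param path input path.
#' @return a data.frame.
#' @export
read_tsv_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
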