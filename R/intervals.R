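## Genomic intervals and peaks.
##
## Every coordinate in this package is 0-based half-open: an interval
## [start, end) covers bases start .. end-1 and has width end - start.
## BED input is taken verbatim; refFlat txStart is already 0-based.
## Contig names match exactly and case-sensitively (no "chr" aliasing).

#' Construct a table of genomic intervals
#'
#' @param chrom contig names.
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded); recycled.
#' @return a data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!nzchar(chrom))) stopf("interval with empty contig name")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stopf("invalid interval at row %d: start=%s end=%s (need 0 <= start < end)",
          bad[1], start[bad[1]], end[bad[1]])
  }
  if (!all(strand %in% c("+", "-", "*"))) stopf("strand must be +, - or *")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(strand, length(chrom)),
             stringsAsFactors = FALSE)
}

#' Construct a peak table
#'
#' A peak is a genomic interval with a non-negative peak-caller score and a
#' condition label (e.g. `"untreated"`, `"T3"`).
#'
#' @inheritParams genomic_intervals
#' @param score non-negative enrichment scores; recycled.
#' @param condition condition label; recycled.
#' @param name optional peak names.
#' @return a data.frame with columns `chrom,start,end,name,score,condition`.
#' @export
peaks_table <- function(chrom, start, end, score = 0, condition = "peak",
                        name = NULL) {
  iv <- genomic_intervals(chrom, start, end)
  score <- rep_len(as.numeric(score), nrow(iv))
  if (any(score < 0)) stopf("peak scores must be >= 0")
  name <- if (is.null(name)) sprintf("peak_%d", seq_len(nrow(iv))) else
    rep_len(as.character(name), nrow(iv))
  cbind(iv[c("chrom", "start", "end")],
        data.frame(name = name, score = score,
                   condition = rep_len(as.character(condition), nrow(iv)),
                   stringsAsFactors = FALSE))
}

interval_width <- function(iv) iv$end - iv$start

interval_midpoint <- function(iv) floor((iv$start + iv$end) / 2)

## convert 0-based half-open rows to an IRanges (1-based closed)
as_iranges0 <- function(iv) {
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

## convert an IRanges back to 0-based half-open columns
from_iranges0 <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merge overlapping intervals per contig
#'
#' @param iv an interval data.frame.
#' @return merged intervals (strand dropped), sorted by (chrom, start).
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(genomic_intervals(character(), numeric(), numeric())[0, ])
  out <- lapply(split(iv, iv$chrom), function(d) {
    r <- from_iranges0(IRanges::reduce(as_iranges0(d)))
    data.frame(chrom = d$chrom[1], r, strand = "*", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Subtract one interval set from another (per contig)
#'
#' @param iv intervals to keep (minuend).
#' @param remove intervals to subtract.
#' @return the parts of `iv` not covered by `remove`.
#' @export
setdiff_intervals <- function(iv, remove) {
  if (nrow(remove) == 0) return(merge_intervals(iv))
  out <- lapply(split(iv, iv$chrom), function(d) {
    rm <- remove[remove$chrom == d$chrom[1], , drop = FALSE]
    ir <- IRanges::setdiff(as_iranges0(d), as_iranges0(rm))
    if (length(ir) == 0) return(NULL)
    data.frame(chrom = d$chrom[1], from_iranges0(ir), strand = "*",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(genomic_intervals(character(), numeric(), numeric())[0, ])
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
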