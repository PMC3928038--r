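## Readers and writers for the formats the pipeline touches:
## FASTA (genome), BED3/BED5 (peaks), refFlat (gene models), expression TSV.

#' Read a FASTA file into a sequence set
#'
#' Sequences are uppercased (lowercase input is accepted and folded); `N`
#' bases are preserved. A sequence set is a named character vector,
#' contig name -> DNA string over `{A,C,G,T,N}`.
#'
#' @param path path to a (multi-record, possibly wrapped) FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stopf("malformed FASTA '%s': %s",
                                           path, conditionMessage(e)))
  if (length(ss) == 0) stopf("malformed FASTA '%s': no records", path)
  out <- toupper(as.character(ss))
  ## keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(names(out)))) stopf("malformed FASTA '%s': empty header", path)
  out
}

#' Write a sequence set to FASTA
#'
#' @param genome named character vector of DNA strings.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a BED3/BED5 file as a peak table
#'
#' Coordinates are 0-based half-open and preserved verbatim. A missing score
#' column yields score 0. Columns beyond the fifth are ignored. Set
#' `one_based = TRUE` for peak-table dialects whose starts are 1-based
#' inclusive; they are shifted to the internal convention at read time.
#'
#' @param path BED path (`#` comment and `track` lines skipped).
#' @param condition condition label attached to every peak.
#' @param one_based if TRUE, input starts are 1-based inclusive.
#' @return a peak table (see [peaks_table()]).
#' @export
read_bed <- function(path, condition = "peak", one_based = FALSE) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]; lineno <- which(keep)
  if (length(lines) == 0) {
    return(peaks_table(character(), numeric(), numeric())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stopf("BED record with <3 columns at line %d of %s", lineno[which(nf < 3)[1]], path)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stopf("non-numeric BED coordinate at line %d of %s",
          lineno[which(is.na(start) | is.na(end))[1]], path)
  }
  if (one_based) start <- start - 1
  bad <- which(start >= end)
  if (length(bad)) {
    stopf("BED record with start >= end at line %d of %s", lineno[bad[1]], path)
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA)
  name[is.na(name) | !nzchar(name)] <- paste0("peak_", which(is.na(name) | !nzchar(name)))
  score <- rep(0, length(lines))
  has5 <- nf >= 5
  score[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[`, "", 5L)))
  score[is.na(score)] <- 0
  peaks_table(chrom, start, end, score = score, condition = condition, name = name)
}

#' Write a peak table as BED5
#' @param peaks a peak table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
                   format(peaks$end, scientific = FALSE, trim = TRUE),
                   peaks$name, peaks$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a refFlat gene-annotation file
#'
#' Columns: geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds. txStart is 0-based; the TSS is txStart on
#' the + strand and txEnd - 1 on the - strand.
#'
#' @param path refFlat path.
#' @return a gene-model data.frame with columns `gene_id, chrom, strand,
#'   tx_start, tx_end, cds_start, cds_end, tss` and list columns
#'   `exon_starts`, `exon_ends`.
#' @export
read_refflat <- function(path) {
  if (!file.exists(path)) stopf("refFlat file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11)) {
    stopf("refFlat record with <11 columns at line %d of %s",
          which(lengths(fields) < 11)[1], path)
  }
  parse_csv_ints <- function(x) as.numeric(strsplit(sub(",$", "", x), ",")[[1]])
  gm <- data.frame(
    gene_id = vapply(fields, `[`, "", 1L),
    chrom = vapply(fields, `[`, "", 3L),
    strand = vapply(fields, `[`, "", 4L),
    tx_start = as.numeric(vapply(fields, `[`, "", 5L)),
    tx_end = as.numeric(vapply(fields, `[`, "", 6L)),
    cds_start = as.numeric(vapply(fields, `[`, "", 7L)),
    cds_end = as.numeric(vapply(fields, `[`, "", 8L)),
    stringsAsFactors = FALSE)
  n_exons <- as.integer(vapply(fields, `[`, "", 9L))
  gm$exon_starts <- lapply(fields, function(f) parse_csv_ints(f[10]))
  gm$exon_ends <- lapply(fields, function(f) parse_csv_ints(f[11]))
  bad <- which(lengths(gm$exon_starts) != n_exons | lengths(gm$exon_ends) != n_exons)
  if (length(bad)) {
    stopf("refFlat exonCount mismatch for gene '%s' (line %d of %s)",
          gm$gene_id[bad[1]], bad[1], path)
  }
  validate_gene_models(gm)
  gm$tss <- ifelse(gm$strand == "+", gm$tx_start, gm$tx_end - 1)
  gm
}

validate_gene_models <- function(gm) {
  if (!all(gm$strand %in% c("+", "-"))) stopf("gene models require strand + or -")
  if (any(gm$tx_start >= gm$tx_end)) stopf("gene model with txStart >= txEnd")
  if (any(gm$cds_start > gm$cds_end)) stopf("gene model with cdsStart > cdsEnd")
  for (i in seq_len(nrow(gm))) {
    s <- gm$exon_starts[[i]]; e <- gm$exon_ends[[i]]
    if (any(s >= e) || is.unsorted(s, strictly = TRUE) ||
        any(s[-1] < e[-length(e)]) ||
        s[1] < gm$tx_start[i] || e[length(e)] > gm$tx_end[i]) {
      stopf("gene '%s': exons must be sorted, non-overlapping and within the transcript",
            gm$gene_id[i])
    }
  }
  invisible(gm)
}

#' Write gene models in refFlat layout
#' @param gm a gene-model data.frame (see [read_refflat()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(gm, path) {
  num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  csv <- function(xs) vapply(xs, function(x) paste0(paste(num(x), collapse = ","), ","), "")
  lines <- paste(gm$gene_id, gm$gene_id, gm$chrom, gm$strand,
                 num(gm$tx_start), num(gm$tx_end), num(gm$cds_start), num(gm$cds_end),
                 lengths(gm$exon_starts), csv(gm$exon_starts), csv(gm$exon_ends),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Extract plus-strand sequences for a set of intervals
#'
#' The plus-strand sequence is returned regardless of interval strand;
#' bidirectional handling is the scanner's job.
#'
#' @param intervals an interval or peak data.frame.
#' @param genome a sequence set from [read_fasta()] or [simulate_genome()].
#' @return character vector of DNA strings, one per interval.
#' @export
extract_sequences <- function(intervals, genome) {
  if (nrow(intervals) == 0) return(character())
  unknown <- setdiff(unique(intervals$chrom), names(genome))
  if (length(unknown)) stopf("unknown contig '%s' in interval set", unknown[1])
  clen <- nchar(genome)[intervals$chrom]
  bad <- which(intervals$end > clen)
  if (length(bad)) {
    stopf("interval %s:[%s,%s) extends past contig end (%d bp)",
          intervals$chrom[bad[1]], intervals$start[bad[1]],
          intervals$end[bad[1]], clen[bad[1]])
  }
  unname(substring(genome[intervals$chrom], intervals$start + 1, intervals$end))
}

#' Read an expression matrix TSV
#'
#' Layout: a header row `gene_id<TAB>sample1<TAB>...`, one row per gene.
#'
#' @param path TSV path.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stopf("non-numeric expression values in sample column '%s'", colnames(df)[bad + 1])
  }
  rownames(m) <- df[[1]]
  m
}

#' Write an expression matrix TSV
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
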