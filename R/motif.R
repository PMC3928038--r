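## IUPAC half-site and dyad (two half-sites + spacer) grammar scanning.
##
## Response elements of nuclear receptors are built from AGGTCA-like
## half-sites arranged as direct, everted or inverted repeats with a
## characteristic spacer (DR-n / ER-n / IP-n). The grammar here mirrors that
## notation: a motif is either a single IUPAC word ("AGGTCA") or a dyad
## "LEFT-k-RIGHT" / "LEFT-a..b-RIGHT" where k (or the inclusive range a..b)
## is the spacer length in bp and the spacer bases are unconstrained.
##
## Matching semantics for the unknown base: the pattern code `n` matches N
## in the genome; every other IUPAC code (including A,C,G,T and two- or
## three-base codes) does NOT match N — an unknown base never satisfies a
## specific-base requirement. Spacer positions match anything including N.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D", N = "N")

#' Reverse complement of a DNA string or IUPAC pattern
#'
#' An involution over the full IUPAC alphabet (R<->Y, S<->S, W<->W, K<->M,
#' B<->V, D<->H, N<->N). Input case is folded to uppercase.
#'
#' @param x character vector of DNA/IUPAC strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", x)
  if (any(bad)) {
    ch <- regmatches(x[bad][1], regexpr("[^ACGTRYSWKMBDHVN]", x[bad][1]))
    stopf("invalid character '%s' in DNA/IUPAC string", ch)
  }
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Parse the half-site / dyad motif notation
#'
#' Accepts `HALF`, `HALF-k-HALF` and `HALF-a..b-HALF`, e.g. `"AGGTCA"`,
#' `"AGGnCA-4-AGGnCA"` (a DR4 element), `"AGGnCA-0..12-AGGnCA"`.
#'
#' @param text one notation string.
#' @param label optional motif label carried into results.
#' @return an object of class `iupac_pattern` (fields `pattern`, `label`) or
#'   `dyad_spec` (fields `left`, `spacer_min`, `spacer_max`, `right`, `label`).
#' @export
parse_motif_notation <- function(text, label = text) {
  text <- trimws(text)
  word <- "[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+"
  if (grepl(sprintf("^%s$", word), text)) {
    pat <- toupper(text)
    return(structure(list(pattern = pat, label = label),
                     class = "iupac_pattern"))
  }
  m <- regexec(sprintf("^(%s)-([0-9]+)(\\.\\.([0-9]+))?-(%s)$", word, word), text)
  g <- regmatches(text, m)[[1]]
  if (length(g) == 0) {
    stopf("cannot parse motif notation '%s' (expected HALF, HALF-k-HALF or HALF-a..b-HALF)",
          text)
  }
  a <- as.integer(g[3])
  b <- if (nzchar(g[5])) as.integer(g[5]) else a
  if (b < a) stopf("motif '%s': spacer range upper bound below lower bound", text)
  structure(list(left = toupper(g[2]), spacer_min = a, spacer_max = b,
                 right = toupper(g[6]), label = label),
            class = "dyad_spec")
}

#' Render a parsed motif back to its notation string
#' @param motif a parsed motif.
#' @return the notation string.
#' @export
motif_notation <- function(motif) {
  if (inherits(motif, "iupac_pattern")) return(motif$pattern)
  sp <- if (motif$spacer_min == motif$spacer_max) motif$spacer_min else
    sprintf("%d..%d", motif$spacer_min, motif$spacer_max)
  sprintf("%s-%s-%s", motif$left, sp, motif$right)
}

## regex character class for one IUPAC code under the N-matching rule
iupac_class <- function(code) {
  paste0("[", paste(IUPAC_SETS[[code]], collapse = ""), "]")
}

iupac_regex <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], iupac_class, ""), collapse = "")
}

## all overlapping 0-based start offsets of a regex in seq
regex_starts <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  as.integer(m) - 1L
}

match_frame <- function(start, width, strand, seq, spacer = NA_integer_) {
  matched <- if (length(start)) substring(seq, start + 1, start + width)
  else character()
  data.frame(start = start, end = start + width,
             strand = rep_len(strand, length(start)),
             matched = matched, spacer_used = rep_len(spacer, length(start)),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for an IUPAC pattern
#'
#' All overlapping occurrences are reported. With `bidirectional = TRUE` the
#' reverse complement of the pattern is also scanned on the given sequence
#' and reported with strand `-`. A self-reverse-complementary (palindromic)
#' pattern would produce identical footprints on both strands; such sites
#' are reported once, as strand `+`.
#'
#' Coordinates are 0-based half-open offsets into `seq`; `matched` is always
#' the plus-strand footprint sequence.
#'
#' @param seq one DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param pattern an `iupac_pattern`, or a notation string.
#' @param bidirectional scan both strands (default TRUE).
#' @return data.frame with columns `start, end, strand, matched, spacer_used`.
#' @export
scan_pattern <- function(seq, pattern, bidirectional = TRUE) {
  if (is.character(pattern)) pattern <- parse_motif_notation(pattern)
  stopifnot(inherits(pattern, "iupac_pattern"))
  seq <- toupper(seq)
  w <- nchar(pattern$pattern)
  fwd <- match_frame(regex_starts(seq, iupac_regex(pattern$pattern)), w, "+", seq)
  if (!bidirectional) return(fwd)
  rc <- reverse_complement(pattern$pattern)
  if (rc == pattern$pattern) return(fwd)  # palindromic: one biological site
  rev <- match_frame(regex_starts(seq, iupac_regex(rc)), w, "-", seq)
  out <- rbind(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a sequence for a dyad (two half-sites + spacer)
#'
#' A plus-strand match with spacer `s` exists at offset `i` iff the left
#' half matches at `i` and the right half matches at `i + |left| + s`;
#' spacer bases are unconstrained (they may be N). For a spacer range every
#' length is tested and each match records `spacer_used`. Minus-strand
#' matches are matches of the reverse-complemented composite on the plus
#' strand, reported with strand `-`. A composite that is its own reverse
#' complement (rc(right) == left) is reported on the plus strand only.
#'
#' @param seq one DNA string.
#' @param dyad a `dyad_spec`, or a notation string such as
#'   `"AGGnCA-4-AGGnCA"`.
#' @param bidirectional scan both strands (default TRUE).
#' @return data.frame as in [scan_pattern()].
#' @export
scan_dyad <- function(seq, dyad, bidirectional = TRUE) {
  if (is.character(dyad)) dyad <- parse_motif_notation(dyad)
  stopifnot(inherits(dyad, "dyad_spec"))
  seq <- toupper(seq)
  lw <- nchar(dyad$left); rw <- nchar(dyad$right)
  lrx <- iupac_regex(dyad$left); rrx <- iupac_regex(dyad$right)
  rc_l <- reverse_complement(dyad$left); rc_r <- reverse_complement(dyad$right)
  palindromic <- identical(rc_r, dyad$left) && identical(rc_l, dyad$right)
  out <- vector("list", 2 * (dyad$spacer_max - dyad$spacer_min + 1))
  k <- 0
  for (s in dyad$spacer_min:dyad$spacer_max) {
    w <- lw + s + rw
    rx <- paste0(lrx, sprintf("[ACGTN]{%d}", s), rrx)
    k <- k + 1
    out[[k]] <- match_frame(regex_starts(seq, rx), w, "+", seq, spacer = s)
    if (bidirectional && !palindromic) {
      rx_rc <- paste0(iupac_regex(rc_r), sprintf("[ACGTN]{%d}", s), iupac_regex(rc_l))
      k <- k + 1
      out[[k]] <- match_frame(regex_starts(seq, rx_rc), w, "-", seq, spacer = s)
    }
  }
  out <- do.call(rbind, out[seq_len(k)])
  out[order(out$start, out$spacer_used, out$strand), , drop = FALSE]
}

#' Scan a sequence for any parsed motif
#'
#' Dispatches to [scan_pattern()] or [scan_dyad()].
#'
#' @inheritParams scan_pattern
#' @param motif a parsed motif or notation string.
#' @return data.frame as in [scan_pattern()].
#' @export
scan_motif <- function(seq, motif, bidirectional = TRUE) {
  if (is.character(motif)) motif <- parse_motif_notation(motif)
  if (inherits(motif, "dyad_spec")) scan_dyad(seq, motif, bidirectional)
  else scan_pattern(seq, motif, bidirectional)
}

#' Read a motif grammar file
#'
#' One motif per line, `LABEL<TAB>NOTATION`; `#` starts a comment.
#'
#' @param path grammar file path.
#' @return list of parsed motifs, named by label.
#' @export
read_motif_grammar <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2)) {
    stopf("grammar line %d of %s: expected LABEL<TAB>NOTATION",
          which(lengths(fields) != 2)[1], path)
  }
  motifs <- lapply(fields, function(f) parse_motif_notation(f[2], label = f[1]))
  names(motifs) <- vapply(fields, `[`, "", 1L)
  motifs
}

#' Write motif matches as BED6
#'
#' @param matches a match data.frame from a scan, with columns
#'   `chrom, start, end, strand` (genome coordinates).
#' @param path output path.
#' @param label feature name written in column 4.
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(matches, path, label = "motif") {
  df <- data.frame(matches$chrom,
                   format(matches$start, scientific = FALSE, trim = TRUE),
                   format(matches$end, scientific = FALSE, trim = TRUE),
                   label, 1, matches$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
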