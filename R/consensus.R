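## Position frequency matrix (PFM) derivation from top-ranked peaks by
## seeded alignment, IUPAC consensus calling, and log-odds PWM scanning.
##
## The PFM is built by locating one best seed-pattern match per peak
## sequence (closest to the peak midpoint, minus-strand matches re-oriented
## into seed orientation), extending it by fixed 5'/3' flanks and stacking
## the aligned windows. This is a deterministic replacement for de-novo
## discovery: the seed encodes the known half-site grammar.

BASES <- c("A", "C", "G", "T")

#' Top-n peaks by score
#'
#' Descending by score; ties broken by (chrom, start) so the result is
#' stable across runs.
#'
#' @param peaks a peak table.
#' @param n how many peaks to keep (e.g. the top 150).
#' @return the top-n rows of `peaks`.
#' @export
rank_peaks <- function(peaks, n) {
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  if (n > nrow(peaks)) {
    warning(sprintf("requested top %d peaks but only %d available", n, nrow(peaks)))
    n <- nrow(peaks)
  }
  out <- peaks[ord[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a PFM from peak sequences by seeded alignment
#'
#' For each sequence the seed match closest to the sequence midpoint is
#' taken (minus-strand matches are reverse-complemented into seed
#' orientation), extended by `flank5`/`flank3` bases, and the aligned
#' windows are stacked into per-column base counts. Sequences without a
#' seed match, whose window would run off the sequence, or whose window
#' contains N are skipped.
#'
#' @param peak_seqs character vector of peak sequences.
#' @param seed an `iupac_pattern` (or notation string) used as alignment
#'   anchor, e.g. `"AGGnCA"`.
#' @param flank5,flank3 bases added 5' / 3' of the seed match.
#' @return list of class `pfm`: `counts` (4 x L matrix, rows A/C/G/T),
#'   `n_sequences`, `width`.
#' @export
build_pfm_from_seed <- function(peak_seqs, seed, flank5 = 0, flank3 = 0) {
  stopifnot(flank5 >= 0, flank3 >= 0)
  if (is.character(seed)) seed <- parse_motif_notation(seed)
  stopifnot(inherits(seed, "iupac_pattern"))
  sw <- nchar(seed$pattern)
  L <- flank5 + sw + flank3
  windows <- character()
  for (s in toupper(peak_seqs)) {
    m <- scan_pattern(s, seed, bidirectional = TRUE)
    if (nrow(m) == 0) next
    mid <- nchar(s) / 2
    m <- m[order(abs((m$start + m$end) / 2 - mid), m$start), , drop = FALSE]
    win <- NA_character_
    for (i in seq_len(nrow(m))) {
      if (m$strand[i] == "+") {
        a <- m$start[i] - flank5; b <- m$end[i] + flank3
        if (a < 0 || b > nchar(s)) next
        w <- substring(s, a + 1, b)
      } else {
        ## on the minus strand the seed's 5' flank lies 3' in plus coords
        a <- m$start[i] - flank3; b <- m$end[i] + flank5
        if (a < 0 || b > nchar(s)) next
        w <- reverse_complement(substring(s, a + 1, b))
      }
      if (grepl("N", w, fixed = TRUE)) next
      win <- w
      break
    }
    if (!is.na(win)) windows <- c(windows, win)
  }
  if (length(windows) == 0) stopf("build_pfm_from_seed: no usable seed matches")
  chars <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
                  byrow = TRUE)
  counts <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = BASES))
    as.integer(tab)
  }, integer(4))
  rownames(counts) <- BASES
  structure(list(counts = counts, n_sequences = length(windows), width = L),
            class = "pfm")
}

#' Collapse a PFM to an IUPAC consensus pattern
#'
#' Per column: a single base if its frequency is at least `major_threshold`;
#' otherwise the smallest IUPAC base set whose cumulative frequency reaches
#' `coverage_threshold` (ties broken toward the higher-frequency set, then
#' alphabetically).
#'
#' @param pfm a `pfm` object.
#' @param major_threshold frequency above which a column is a single base.
#' @param coverage_threshold cumulative frequency a degenerate code must
#'   cover.
#' @return an `iupac_pattern`.
#' @export
pfm_to_iupac <- function(pfm, major_threshold = 0.6, coverage_threshold = 0.8) {
  stopifnot(major_threshold > 0, major_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  freqs <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  codes <- names(IUPAC_SETS)
  sets <- IUPAC_SETS
  sizes <- lengths(sets)
  cons <- vapply(seq_len(pfm$width), function(j) {
    f <- freqs[, j]
    top <- which.max(f)
    if (f[top] >= major_threshold) return(BASES[top])
    cum <- vapply(codes, function(cd) sum(f[intersect(sets[[cd]], BASES)]), 0)
    ok <- cum >= coverage_threshold
    if (!any(ok)) return("N")
    cand <- codes[ok]
    cand <- cand[order(sizes[cand], -cum[cand], cand)]
    cand[1]
  }, "")
  parse_motif_notation(paste(cons, collapse = ""))
}

#' Convert a PFM to a log-odds PWM
#'
#' Column log-odds for base b: log2((count_b + pseudocount * bg_b) /
#' (n + pseudocount) / bg_b). The default pseudocount of 1 spread by the
#' background (0.25 per base under a uniform background) keeps log-odds
#' finite.
#'
#' @param pfm a `pfm` object.
#' @param background named base frequencies summing to 1; by default
#'   computed from `genome` if given, else uniform.
#' @param genome optional sequence set whose observed base composition
#'   (ignoring N) becomes the background.
#' @param pseudocount total pseudocount mass.
#' @return list of class `pwm`: `logodds` (4 x L), `background`,
#'   `pseudocount`, `max_score`, `width`.
#' @export
pfm_to_pwm <- function(pfm, background = NULL, genome = NULL, pseudocount = 1) {
  if (is.null(background)) {
    background <- if (is.null(genome)) c(A = .25, C = .25, G = .25, T = .25)
    else genome_base_composition(genome)
  }
  background <- background[BASES]
  stopifnot(abs(sum(background) - 1) < 1e-6, all(background > 0))
  n <- pfm$n_sequences
  lo <- log2(sweep(pfm$counts + pseudocount * background, 1, background, "/") /
               (n + pseudocount))
  structure(list(logodds = lo, background = background,
                 pseudocount = pseudocount,
                 max_score = sum(apply(lo, 2, max)), width = pfm$width),
            class = "pwm")
}

#' Observed base composition of a sequence set (N excluded)
#' @param genome sequence set.
#' @return named frequencies over A, C, G, T.
#' @export
genome_base_composition <- function(genome) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in genome) {
    tab <- table(strsplit(s, "")[[1]])
    for (b in BASES) counts[b] <- counts[b] + (if (b %in% names(tab)) tab[[b]] else 0)
  }
  counts / sum(counts)
}

#' Scan a sequence with a log-odds PWM
#'
#' Every window of PWM width scoring at least `score_fraction * max_score`
#' is reported, on both strands when `bidirectional`. Windows containing N
#' are skipped (their log-odds are undefined). The minus-strand score is
#' the score of the reverse-complemented window against the PWM.
#'
#' @param seq one DNA string.
#' @param pwm a `pwm` object.
#' @param score_fraction report threshold as a fraction of `max_score`.
#' @param bidirectional scan both strands.
#' @return data.frame `start, end, strand, matched, score`, sorted by
#'   position.
#' @export
pwm_scan <- function(seq, pwm, score_fraction = 0.8, bidirectional = TRUE) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  seq <- toupper(seq)
  L <- pwm$width
  n <- nchar(seq)
  empty <- data.frame(start = numeric(), end = numeric(), strand = character(),
                      matched = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  idx <- match(strsplit(seq, "")[[1]], BASES)  # NA for N
  nwin <- n - L + 1
  score_strand <- function(rows) {
    ## rows: for each window offset j (1..L) the logodds row index per base
    sc <- numeric(nwin); ok <- rep(TRUE, nwin)
    for (j in seq_len(L)) {
      b <- idx[j:(j + nwin - 1)]
      ok <- ok & !is.na(b)
      v <- rows[cbind(ifelse(is.na(b), 1L, b), j)]
      sc <- sc + v
    }
    sc[!ok] <- -Inf
    sc
  }
  fwd <- score_strand(pwm$logodds)
  thr <- score_fraction * pwm$max_score
  out <- list()
  keep <- which(fwd >= thr)
  if (length(keep)) {
    out[[1]] <- data.frame(start = keep - 1, end = keep - 1 + L, strand = "+",
                           matched = substring(seq, keep, keep + L - 1),
                           score = fwd[keep], stringsAsFactors = FALSE)
  }
  if (bidirectional) {
    ## score of rc(window) against PWM == score of window against the
    ## reverse-complemented PWM (rows A<->T, C<->G; columns reversed)
    rc_lo <- pwm$logodds[c("T", "G", "C", "A"), rev(seq_len(L)), drop = FALSE]
    rownames(rc_lo) <- BASES
    rev_sc <- score_strand(rc_lo)
    keep <- which(rev_sc >= thr)
    if (length(keep)) {
      out[[length(out) + 1]] <-
        data.frame(start = keep - 1, end = keep - 1 + L, strand = "-",
                   matched = substring(seq, keep, keep + L - 1),
                   score = rev_sc[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Write a PFM in JASPAR-style text format
#'
#' Four rows A/C/G/T of integer counts, preceded by a `>` header.
#'
#' @param pfm a `pfm` object.
#' @param path output path.
#' @param name matrix name for the header.
#' @return `path`, invisibly.
#' @export
write_pfm_jaspar <- function(pfm, path, name = "PFM") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  for (b in BASES) {
    writeLines(sprintf("%s  [ %s ]", b,
                       paste(format(pfm$counts[b, ], width = 4), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a JASPAR-style PFM
#' @param path input path.
#' @return a `pfm` object.
#' @export
read_pfm_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^>", lines)]
  if (length(lines) != 4) stopf("JASPAR PFM '%s': expected 4 base rows", path)
  rows <- lapply(lines, function(l) {
    s <- sub("^\\s*[ACGTacgt]", "", l)
    as.numeric(regmatches(s, gregexpr("[0-9]+(\\.[0-9]+)?", s))[[1]])
  })
  base_of <- toupper(substr(trimws(lines), 1, 1))
  if (!setequal(base_of, BASES)) stopf("JASPAR PFM '%s': rows must be A,C,G,T", path)
  counts <- do.call(rbind, rows[match(BASES, base_of)])
  rownames(counts) <- BASES
  if (length(unique(lengths(rows))) != 1) stopf("JASPAR PFM '%s': ragged rows", path)
  structure(list(counts = counts, n_sequences = sum(counts[, 1]),
                 width = ncol(counts)), class = "pfm")
}
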