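## Length-normalized motif occurrence rates and fold enrichment of peak
## sets over a genomic background, and a permutation co-localization
## z-score for known transcription-factor consensus motifs.

#' Occurrence statistics of a motif over a region set
#'
#' Regions are scanned bidirectionally; a hit is attributed to the region it
#' lies in (scanning is per extracted region, so matches never cross region
#' boundaries). `rate_per_bp` is total hits / total region bp — the
#' length-normalized bidirectional occurrence rate.
#'
#' @param regions an interval or peak data.frame.
#' @param genome a sequence set.
#' @param motif parsed motif or notation string.
#' @return list with fields `n_regions`, `n_regions_with_hit`, `total_hits`,
#'   `total_bp`, `rate_per_bp`, `fraction_with_hit` (NA when `n_regions` is 0).
#' @export
region_occurrences <- function(regions, genome, motif) {
  if (is.character(motif)) motif <- parse_motif_notation(motif)
  n <- nrow(regions)
  if (n == 0) {
    return(list(n_regions = 0L, n_regions_with_hit = 0L, total_hits = 0L,
                total_bp = 0L, rate_per_bp = NA_real_,
                fraction_with_hit = NA_real_))
  }
  seqs <- extract_sequences(regions, genome)
  hits <- vapply(seqs, function(s) nrow(scan_motif(s, motif)), 0L,
                 USE.NAMES = FALSE)
  total_bp <- sum(interval_width(regions))
  list(n_regions = n,
       n_regions_with_hit = sum(hits > 0),
       total_hits = sum(hits),
       total_bp = total_bp,
       rate_per_bp = sum(hits) / total_bp,
       fraction_with_hit = sum(hits > 0) / n)
}

whole_genome_regions <- function(genome) {
  genomic_intervals(names(genome), 0, nchar(genome))
}

#' Fold enrichment of a motif in foreground regions over a background
#'
#' Fold = per-bp bidirectional hit rate in the foreground / same rate in the
#' background. The default background is the whole genome including the
#' foreground (peaks are normally a negligible genome fraction);
#' `exclude_foreground = TRUE` subtracts the merged foreground from the
#' background first. Background bp is counted with overlaps merged.
#'
#' @param foreground foreground regions (e.g. a peak table).
#' @param genome sequence set.
#' @param motif parsed motif or notation string.
#' @param background optional explicit background regions; default whole
#'   genome.
#' @param exclude_foreground subtract foreground from background.
#' @return list with `motif_label`, `foreground`, `background` (both
#'   [region_occurrences()] results) and `fold_enrichment` (NA when the
#'   background rate is 0 — flagged undefined, not an error).
#' @export
fold_enrichment <- function(foreground, genome, motif, background = NULL,
                            exclude_foreground = FALSE) {
  if (is.character(motif)) motif <- parse_motif_notation(motif)
  bg <- if (is.null(background)) whole_genome_regions(genome) else
    merge_intervals(background)
  if (exclude_foreground) bg <- setdiff_intervals(bg, foreground)
  fg_stats <- region_occurrences(foreground, genome, motif)
  bg_stats <- region_occurrences(bg, genome, motif)
  fold <- if (!is.na(bg_stats$rate_per_bp) && bg_stats$rate_per_bp > 0)
    fg_stats$rate_per_bp / bg_stats$rate_per_bp else NA_real_
  list(motif_label = motif$label, foreground = fg_stats,
       background = bg_stats, fold_enrichment = fold)
}

#' Motif occurrence/enrichment report over peak sets per condition
#'
#' One row per (motif, condition): percentage of peaks containing the motif,
#' length-normalized occurrence rates in peaks and in the whole-genome
#' background, and their ratio as fold enrichment. Row order follows the
#' motif list, then the condition list.
#'
#' @param peak_sets named list of peak tables, one per condition.
#' @param genome sequence set.
#' @param motifs list of parsed motifs (see [read_motif_grammar()]).
#' @param exclude_foreground see [fold_enrichment()].
#' @return data.frame with columns `motif_label, notation, condition,
#'   pct_regions_with_hit, n_regions_with_hit, n_regions, rate_per_bp,
#'   background_rate_per_bp, fold_enrichment`.
#' @export
table1_report <- function(peak_sets, genome, motifs, exclude_foreground = FALSE) {
  stopifnot(length(peak_sets) >= 1, length(names(peak_sets)) == length(peak_sets))
  rows <- list()
  for (m in motifs) {
    for (cond in names(peak_sets)) {
      fe <- tryCatch(
        fold_enrichment(peak_sets[[cond]], genome, m,
                        exclude_foreground = exclude_foreground),
        error = function(e) stopf("motif '%s': %s", m$label, conditionMessage(e)))
      rows[[length(rows) + 1]] <- data.frame(
        motif_label = m$label, notation = motif_notation(m), condition = cond,
        pct_regions_with_hit = 100 * fe$foreground$fraction_with_hit,
        n_regions_with_hit = fe$foreground$n_regions_with_hit,
        n_regions = fe$foreground$n_regions,
        rate_per_bp = fe$foreground$rate_per_bp,
        background_rate_per_bp = fe$background$rate_per_bp,
        fold_enrichment = fe$fold_enrichment,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## all genome-wide match footprints of a motif, per contig:
## data.frame(chrom, start, width). Used by the permutation null so placed
## windows can be counted without rescanning.
genome_match_footprints <- function(genome, motif) {
  out <- lapply(names(genome), function(cn) {
    m <- scan_motif(genome[[cn]], motif)
    if (nrow(m) == 0) return(NULL)
    data.frame(chrom = cn, start = m$start, width = m$end - m$start,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) data.frame(chrom = character(), start = numeric(),
                               width = numeric()) else out
}

## count motif footprints fully inside each of a set of windows
count_hits_in_windows <- function(foot, windows) {
  if (nrow(foot) == 0 || nrow(windows) == 0) return(integer(nrow(windows)))
  n <- integer(nrow(windows))
  for (cn in unique(windows$chrom)) {
    wi <- which(windows$chrom == cn)
    f <- foot[foot$chrom == cn, , drop = FALSE]
    if (nrow(f) == 0) next
    for (w in split(f, f$width)) {
      st <- sort(w$start)
      ## footprint [s, s+width) inside window [a, b) iff a <= s <= b - width
      lo <- findInterval(windows$start[wi] - 1, st)
      hi <- findInterval(windows$end[wi] - w$width[1], st)
      n[wi] <- n[wi] + pmax(0L, hi - lo)
    }
  }
  n
}

#' Permutation z-score for motif co-localization with peaks
#'
#' The observed bidirectional hit count inside the peaks is compared with a
#' null distribution obtained by dropping equally many length-matched
#' windows uniformly on the genome, `n_permutations` times;
#' z = (obs - mean_null) / sd_null. Null placements re-draw (up to 50
#' tries) any window more than half-covered by N runs, so assembly-gap-like
#' regions do not deflate the null.
#'
#' @param peaks a peak table (>= 1 peak).
#' @param genome sequence set.
#' @param motif parsed motif or notation string.
#' @param n_permutations number of null placements (>= 100).
#' @param seed integer seed for reproducibility.
#' @return list with `observed`, `null_mean`, `null_sd`, `z` (NA when the
#'   null sd is 0) and `n_permutations`.
#' @export
colocalization_z <- function(peaks, genome, motif, n_permutations = 1000,
                             seed = 1) {
  if (nrow(peaks) == 0) stopf("colocalization_z: empty peak set")
  if (n_permutations < 100) stopf("colocalization_z: need >= 100 permutations")
  if (is.character(motif)) motif <- parse_motif_notation(motif)
  foot <- genome_match_footprints(genome, motif)
  obs <- sum(count_hits_in_windows(foot, peaks))
  clen <- nchar(genome)
  widths <- interval_width(peaks)
  null_counts <- numeric(n_permutations)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (p in seq_len(n_permutations)) {
    cn <- sample(names(genome), length(widths), replace = TRUE,
                 prob = clen / sum(clen))
    start <- floor(stats::runif(length(widths)) * (clen[cn] - widths))
    win <- data.frame(chrom = cn, start = start, end = start + widths,
                      stringsAsFactors = FALSE)
    ## re-draw windows that are mostly N (assembly-gap avoidance)
    for (tries in 1:50) {
      frac_n <- vapply(gregexpr("N", extract_sequences(win, genome), fixed = TRUE),
                       function(g) if (g[1] == -1) 0L else length(g), 0L) / widths
      bad <- which(frac_n > 0.5)
      if (!length(bad)) break
      cn2 <- sample(names(genome), length(bad), replace = TRUE,
                    prob = clen / sum(clen))
      win$chrom[bad] <- cn2
      win$start[bad] <- floor(stats::runif(length(bad)) * (clen[cn2] - widths[bad]))
      win$end[bad] <- win$start[bad] + widths[bad]
    }
    null_counts[p] <- sum(count_hits_in_windows(foot, win))
  }
  mu <- mean(null_counts); sdv <- stats::sd(null_counts)
  list(observed = obs, null_mean = mu, null_sd = sdv,
       z = if (sdv > 0) (obs - mu) / sdv else NA_real_,
       n_permutations = n_permutations)
}

## save/restore the global RNG state so seeded helpers do not perturb
## the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
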