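## Genomic feature classification of peaks and the genome.
##
## A single precedence-resolved feature map (disjoint intervals per class)
## drives both per-peak classification (by peak midpoint) and per-base
## genome composition, so the two can never disagree. Precedence:
## promoter > five_utr > three_utr > exon > intron > downstream >
## intergenic, with promoter = the promoter_bp bases upstream of the TSS
## (strand-aware) and downstream = downstream_bp past the transcript end.

FEATURE_CLASSES <- c("promoter", "five_utr", "three_utr", "exon", "intron",
                     "downstream", "intergenic")

#' Build the precedence-resolved feature map of a genome annotation
#'
#' @param gene_models gene-model data.frame (see [read_refflat()]).
#' @param contig_lengths named vector of contig lengths.
#' @param promoter_bp promoter extent upstream of the TSS (default 5000).
#' @param downstream_bp downstream extent past the transcript end.
#' @return list of class `feature_map`: per class, a data.frame of disjoint
#'   intervals; plus `contig_lengths`, `promoter_bp`, `downstream_bp`.
#' @export
feature_map <- function(gene_models, contig_lengths, promoter_bp = 5000,
                        downstream_bp = 5000) {
  gm <- gene_models
  if (nrow(gm) > 0 &&
      any(gm$tx_end > contig_lengths[gm$chrom] | gm$tx_start < 0)) {
    stopf("gene model extends past its contig")
  }
  clip <- function(iv) {
    if (nrow(iv) == 0) return(iv)
    iv$start <- pmax(0, iv$start)
    iv$end <- pmin(contig_lengths[iv$chrom], iv$end)
    iv[iv$start < iv$end, , drop = FALSE]
  }
  iv0 <- function() data.frame(chrom = character(), start = numeric(),
                               end = numeric(), stringsAsFactors = FALSE)
  raw <- list()
  if (nrow(gm) == 0) {
    raw <- stats::setNames(rep(list(iv0()), 6), FEATURE_CLASSES[1:6])
  } else {
    plus <- gm$strand == "+"
    raw$promoter <- data.frame(
      chrom = gm$chrom,
      start = ifelse(plus, gm$tx_start - promoter_bp, gm$tx_end),
      end = ifelse(plus, gm$tx_start, gm$tx_end + promoter_bp))
    raw$downstream <- data.frame(
      chrom = gm$chrom,
      start = ifelse(plus, gm$tx_end, gm$tx_start - downstream_bp),
      end = ifelse(plus, gm$tx_end + downstream_bp, gm$tx_start))
    ex <- data.frame(
      chrom = rep(gm$chrom, lengths(gm$exon_starts)),
      start = unlist(gm$exon_starts), end = unlist(gm$exon_ends),
      gene = rep(seq_len(nrow(gm)), lengths(gm$exon_starts)))
    ## UTRs are the exonic parts outside the CDS, 5' vs 3' by strand
    cs <- gm$cds_start[ex$gene]; ce <- gm$cds_end[ex$gene]
    gplus <- plus[ex$gene]
    utr_left <- data.frame(chrom = ex$chrom, start = ex$start,
                           end = pmin(ex$end, cs))
    utr_right <- data.frame(chrom = ex$chrom, start = pmax(ex$start, ce),
                            end = ex$end)
    utr_left <- utr_left[utr_left$start < utr_left$end, , drop = FALSE]
    utr_right <- utr_right[utr_right$start < utr_right$end, , drop = FALSE]
    lplus <- gplus[as.integer(rownames(utr_left))]
    rplus <- gplus[as.integer(rownames(utr_right))]
    raw$five_utr <- rbind(utr_left[lplus, , drop = FALSE],
                          utr_right[!rplus, , drop = FALSE])
    raw$three_utr <- rbind(utr_right[rplus, , drop = FALSE],
                           utr_left[!lplus, , drop = FALSE])
    cds_ex <- data.frame(chrom = ex$chrom, start = pmax(ex$start, cs),
                         end = pmin(ex$end, ce))
    ## noncoding transcripts (cds_start == cds_end): whole exons count as exon
    noncode <- cs == ce
    cds_ex$start[noncode] <- ex$start[noncode]
    cds_ex$end[noncode] <- ex$end[noncode]
    raw$exon <- cds_ex[cds_ex$start < cds_ex$end, , drop = FALSE]
    raw$intron <- data.frame(chrom = gm$chrom, start = gm$tx_start,
                             end = gm$tx_end)
  }
  raw <- lapply(raw, clip)
  ## resolve precedence: each class keeps only bases not claimed above it
  resolved <- list()
  claimed <- iv0()
  for (cls in FEATURE_CLASSES[1:6]) {
    iv <- raw[[cls]]
    iv <- if (nrow(iv) == 0) iv0() else
      merge_intervals(genomic_intervals(iv$chrom, iv$start, iv$end))
    keep <- setdiff_intervals(iv, claimed)
    resolved[[cls]] <- keep[c("chrom", "start", "end")]
    claimed <- merge_intervals(rbind(claimed[, c("chrom", "start", "end")],
                                     keep[, c("chrom", "start", "end")],
                                     make.row.names = FALSE))
    claimed$strand <- NULL
  }
  genome_iv <- data.frame(chrom = names(contig_lengths), start = 0,
                          end = as.numeric(contig_lengths))
  resolved$intergenic <- setdiff_intervals(genome_iv, claimed)[c("chrom", "start", "end")]
  structure(c(resolved, list(contig_lengths = contig_lengths,
                             promoter_bp = promoter_bp,
                             downstream_bp = downstream_bp)),
            class = "feature_map")
}

## class of a set of (chrom, pos) points under the map
classify_points <- function(fmap, chrom, pos) {
  out <- rep("intergenic", length(chrom))
  undecided <- rep(TRUE, length(chrom))
  for (cls in FEATURE_CLASSES[1:6]) {
    iv <- fmap[[cls]]
    if (nrow(iv) == 0) next
    for (cn in unique(chrom[undecided])) {
      sel <- which(undecided & chrom == cn)
      ivc <- iv[iv$chrom == cn, , drop = FALSE]
      if (nrow(ivc) == 0) next
      ## pos inside [start,end): count of starts <= pos minus ends <= pos
      inside <- findInterval(pos[sel], sort(ivc$start)) >
        findInterval(pos[sel], sort(ivc$end))
      out[sel[inside]] <- cls
      undecided[sel[inside]] <- FALSE
    }
  }
  factor(out, levels = FEATURE_CLASSES)
}

#' Classify peaks into genomic feature classes
#'
#' Each peak is classified by its midpoint so the class fractions form a
#' partition (they sum to 100%).
#'
#' @param peaks a peak table.
#' @param fmap a [feature_map()], or gene models (then `contig_lengths`
#'   is required and a map is built with the default extents).
#' @param contig_lengths named contig lengths (only if `fmap` is a
#'   gene-model data.frame).
#' @param ... passed to [feature_map()] in that case.
#' @return factor of feature classes, one per peak.
#' @export
classify_peaks <- function(peaks, fmap, contig_lengths = NULL, ...) {
  if (!inherits(fmap, "feature_map")) {
    fmap <- feature_map(fmap, contig_lengths, ...)
  }
  classify_points(fmap, peaks$chrom, interval_midpoint(peaks))
}

#' Per-class genome bp fractions under the precedence map
#'
#' @param fmap a [feature_map()].
#' @return named numeric vector over the seven classes, summing to 1.
#' @export
genome_feature_fractions <- function(fmap) {
  total <- sum(as.numeric(fmap$contig_lengths))
  bp <- vapply(FEATURE_CLASSES, function(cls) {
    iv <- fmap[[cls]]
    if (nrow(iv) == 0) 0 else sum(iv$end - iv$start)
  }, 0)
  bp / total
}

#' Feature-class distribution of peaks and enrichment over the genome
#'
#' Fold = class share of peaks / class share of genome bp, the Fig-1B-style
#' relative enrichment of bound regions within each genomic interval class.
#'
#' @param peaks a peak table (>= 1 peak).
#' @param fmap a [feature_map()].
#' @return data.frame `class, n_peaks, pct_peaks, pct_genome, fold`
#'   (fold is NA when a class has zero genome share but nonzero peaks).
#' @export
feature_enrichment <- function(peaks, fmap) {
  if (nrow(peaks) == 0) stopf("feature_enrichment: empty peak set")
  cls <- classify_peaks(peaks, fmap)
  peak_frac <- as.numeric(table(cls)) / nrow(peaks)
  genome_frac <- genome_feature_fractions(fmap)
  fold <- ifelse(genome_frac > 0, peak_frac / genome_frac,
                 ifelse(peak_frac > 0, NA_real_, 0))
  data.frame(class = FEATURE_CLASSES,
             n_peaks = as.integer(table(cls)),
             pct_peaks = 100 * peak_frac,
             pct_genome = 100 * genome_frac,
             fold = fold, stringsAsFactors = FALSE)
}

#' TSS-relative frequency profile of peak midpoints
#'
#' For each peak midpoint the signed, orientation-corrected distance to the
#' nearest TSS is computed (negative = upstream of the gene); distances are
#' binned over \[-W, +W). Peaks farther than W from every TSS are excluded.
#'
#' @param peaks a peak table.
#' @param gene_models gene-model data.frame.
#' @param W window half-width in bp (multiple of `bin`).
#' @param bin bin size in bp.
#' @return data.frame `bin_start, bin_center, count`; attribute `n_used`
#'   gives the number of contributing peaks.
#' @export
tss_profile <- function(peaks, gene_models, W = 10000, bin = 200) {
  stopifnot(W %% bin == 0)
  d <- rep(NA_real_, nrow(peaks))
  mid <- interval_midpoint(peaks)
  for (cn in unique(peaks$chrom)) {
    g <- gene_models[gene_models$chrom == cn, , drop = FALSE]
    sel <- which(peaks$chrom == cn)
    if (nrow(g) == 0) next
    for (i in sel) {
      signed <- ifelse(g$strand == "+", mid[i] - g$tss, g$tss - mid[i])
      d[i] <- signed[which.min(abs(signed))]
    }
  }
  d <- d[!is.na(d) & d >= -W & d < W]
  breaks <- seq(-W, W, by = bin)
  counts <- as.integer(table(cut(d, breaks, right = FALSE)))
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_center = breaks[-length(breaks)] + bin / 2,
                    count = counts)
  attr(out, "n_used") <- length(d)
  out
}

#' Condition overlap (Venn) of two peak sets
#'
#' A peak is shared iff it reciprocally overlaps some peak of the other set
#' by at least `min_overlap_frac` of each peak's length (the default, 0,
#' means any overlap of >= 1 bp). The unchanged fraction is the fraction of
#' all peaks (both sets pooled) that are shared.
#'
#' @param peaks_a,peaks_b peak tables.
#' @param min_overlap_frac required reciprocal overlap fraction in \[0, 1).
#' @return list `a_only, shared_a, shared_b, b_only, fraction_shared`.
#' @export
condition_overlap <- function(peaks_a, peaks_b, min_overlap_frac = 0) {
  shared_flags <- function(x, y) {
    hit <- rep(FALSE, nrow(x))
    for (cn in unique(x$chrom)) {
      xi <- which(x$chrom == cn)
      yc <- y[y$chrom == cn, , drop = FALSE]
      if (nrow(yc) == 0) next
      ov <- IRanges::findOverlaps(as_iranges0(x[xi, , drop = FALSE]),
                                  as_iranges0(yc))
      if (length(ov) == 0) next
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      w <- pmin(x$end[xi][qi], yc$end[si]) - pmax(x$start[xi][qi], yc$start[si])
      okq <- w / (x$end[xi][qi] - x$start[xi][qi]) >= min_overlap_frac
      oks <- w / (yc$end[si] - yc$start[si]) >= min_overlap_frac
      ok <- if (min_overlap_frac > 0) okq & oks else w >= 1
      hit[xi[unique(qi[ok])]] <- TRUE
    }
    hit
  }
  sa <- shared_flags(peaks_a, peaks_b)
  sb <- shared_flags(peaks_b, peaks_a)
  list(a_only = sum(!sa), shared_a = sum(sa), shared_b = sum(sb),
       b_only = sum(!sb),
       fraction_shared = (sum(sa) + sum(sb)) /
         max(1, nrow(peaks_a) + nrow(peaks_b)))
}
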