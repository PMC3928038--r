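## Expression normalization, regulated-gene calls, and peak-to-gene
## association at fixed TSS distance cutoffs.

#' Normalize a raw intensity matrix
#'
#' Applies `log2(x + offset)` and then quantile normalization (each
#' sample's sorted values replaced by the cross-sample rank means; tied
#' values share the mean of their rank means). With a single sample only
#' the log transform is applied. The offset stabilizes the log transform
#' for low bead intensities.
#'
#' @param raw non-negative intensity matrix, genes x samples.
#' @param offset additive offset before the log2 transform (default 50).
#' @return normalized log2 matrix of the same shape.
#' @export
normalize_expression <- function(raw, offset = 50) {
  if (!is.numeric(raw)) {
    ij <- which(!vapply(as.data.frame(raw), is.numeric, logical(1)))[1]
    stopf("non-numeric expression values in column %d", ij)
  }
  if (any(raw < 0)) stopf("negative raw intensities")
  m <- log2(raw + offset)
  if (ncol(m) <= 1) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Call regulated genes from a normalized expression matrix
#'
#' Per-gene two-group comparison on normalized log2 values with
#' Benjamini-Hochberg adjustment across all genes. A gene is `induced`
#' when its linear fold change (2^(mean_b - mean_a)) is at least
#' `fold_cutoff` and adjusted p < `alpha`; `repressed` symmetrically;
#' otherwise `unchanged`.
#'
#' The default test is limma's moderated t (empirical-Bayes shrinkage of
#' the per-gene variance), the standard for bead-array designs with few
#' replicates; `method = "welch"` gives an unmoderated Welch t-test.
#'
#' @param expr normalized matrix from [normalize_expression()].
#' @param groups character vector of group labels, one per column.
#' @param group_a,group_b labels of the two compared groups (fold is
#'   b over a).
#' @param fold_cutoff linear fold-change cutoff (default 1.7).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param method `"moderated"` (limma) or `"welch"`.
#' @return data.frame `gene_id, log2_fold_change, p_value, adj_p, call`.
#' @export
differential_calls <- function(expr, groups, group_a, group_b,
                               fold_cutoff = 1.7, alpha = 0.05,
                               method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(length(groups) == ncol(expr))
  a <- which(groups == group_a); b <- which(groups == group_b)
  if (length(a) < 2 || length(b) < 2) {
    stopf("differential_calls: both groups need >= 2 samples")
  }
  x <- expr[, a, drop = FALSE]; y <- expr[, b, drop = FALSE]
  lfc <- rowMeans(y) - rowMeans(x)
  if (method == "moderated") {
    design <- cbind(intercept = 1, grp = rep(c(0, 1), c(length(a), length(b))))
    fit <- limma::eBayes(limma::lmFit(cbind(x, y), design))
    p <- fit$p.value[, "grp"]
  } else {
    vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
    se2 <- vx / length(a) + vy / length(b)
    tt <- lfc / sqrt(se2)
    df <- se2^2 / ((vx / length(a))^2 / (length(a) - 1) +
                     (vy / length(b))^2 / (length(b) - 1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    p[se2 == 0] <- ifelse(lfc[se2 == 0] == 0, 1, 0)
  }
  adj <- stats::p.adjust(p, method = "BH")
  call <- ifelse(adj < alpha & lfc >= log2(fold_cutoff), "induced",
                 ifelse(adj < alpha & lfc <= -log2(fold_cutoff), "repressed",
                        "unchanged"))
  data.frame(gene_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             log2_fold_change = unname(lfc), p_value = unname(p),
             adj_p = unname(adj), call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

## gap in bp between a TSS coordinate and a peak [s, e): 0 when the TSS
## lies inside the peak, otherwise distance to the nearer peak boundary
tss_peak_gap <- function(tss, start, end) {
  ifelse(tss < start, start - tss, ifelse(tss >= end, tss - end, 0))
}

## per-gene minimum gap to any peak (same contig)
min_gap_to_peaks <- function(gene_models, peaks) {
  gap <- rep(Inf, nrow(gene_models))
  for (cn in unique(gene_models$chrom)) {
    gi <- which(gene_models$chrom == cn)
    pc <- peaks[peaks$chrom == cn, , drop = FALSE]
    if (nrow(pc) == 0) next
    gap[gi] <- vapply(gene_models$tss[gi], function(t)
      min(tss_peak_gap(t, pc$start, pc$end)), 0)
  }
  gap
}

#' Gene-class x distance association of peaks with gene TSS
#'
#' For each regulation class, the fraction of genes with at least one peak
#' whose gap to the gene's TSS is at most d, for each distance cutoff.
#' "Unaffected" genes are a clean null class: adjusted p >= `null_min_adj_p`
#' and linear |fold| < `null_max_fold` (not merely "not significant").
#'
#' @param calls output of [differential_calls()].
#' @param gene_models gene-model data.frame; calls whose gene has no model
#'   are excluded (count reported in the `n_missing_model` attribute).
#' @param peaks a peak table.
#' @param distances distance cutoffs in bp (default 1, 5 and 25 kb).
#' @param null_min_adj_p,null_max_fold the unaffected-class definition.
#' @return data.frame `class, distance_bp, n_genes, n_with_peak, pct`.
#' @export
associate_peaks_to_genes <- function(calls, gene_models, peaks,
                                     distances = c(1000, 5000, 25000),
                                     null_min_adj_p = 0.5,
                                     null_max_fold = 1.1) {
  idx <- match(calls$gene_id, gene_models$gene_id)
  missing <- sum(is.na(idx))
  calls <- calls[!is.na(idx), , drop = FALSE]
  gm <- gene_models[idx[!is.na(idx)], , drop = FALSE]
  gap <- min_gap_to_peaks(gm, peaks)
  cls <- ifelse(calls$call != "unchanged", calls$call,
                ifelse(calls$adj_p >= null_min_adj_p &
                         abs(calls$log2_fold_change) < log2(null_max_fold),
                       "unaffected", NA))
  rows <- list()
  for (cl in c("induced", "repressed", "unaffected")) {
    sel <- which(!is.na(cls) & cls == cl)
    for (d in distances) {
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, distance_bp = d, n_genes = length(sel),
        n_with_peak = sum(gap[sel] <= d),
        pct = if (length(sel)) 100 * mean(gap[sel] <= d) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_missing_model") <- missing
  out
}

#' Strongly regulated genes with their binding flags (heatmap table)
#'
#' Rows are genes passing `|linear fold| >= fold_floor` and adjusted
#' p < `alpha`, ordered by log2 fold change descending, with per-group mean
#' normalized expression and boolean peak-within-distance flags.
#'
#' @param calls output of [differential_calls()].
#' @param gene_models gene-model data.frame.
#' @param peaks a peak table.
#' @param expr normalized expression matrix.
#' @param groups group labels per column of `expr`.
#' @param fold_floor linear fold floor (default 2.5).
#' @param alpha adjusted-p threshold.
#' @param distances distance cutoffs for the flags.
#' @return data.frame with gene, per-group means, fold and one
#'   `has_peak_<d>` logical column per distance; empty (header only) when
#'   no gene passes.
#' @export
regulation_binding_heatmap_table <- function(calls, gene_models, peaks, expr,
                                             groups, fold_floor = 2.5,
                                             alpha = 0.05,
                                             distances = c(1000, 5000, 25000)) {
  keep <- abs(calls$log2_fold_change) >= log2(fold_floor) & calls$adj_p < alpha
  sub <- calls[keep, , drop = FALSE]
  sub <- sub[order(-sub$log2_fold_change), , drop = FALSE]
  grp_means <- function(gids) {
    mm <- vapply(unique(groups), function(g)
      rowMeans(expr[gids, groups == g, drop = FALSE]),
      numeric(length(gids)))
    matrix(mm, nrow = length(gids))
  }
  idx <- match(sub$gene_id, gene_models$gene_id)
  gm <- gene_models[idx, , drop = FALSE]
  gap <- if (nrow(gm)) min_gap_to_peaks(gm, peaks) else numeric()
  out <- data.frame(gene_id = sub$gene_id,
                    log2_fold_change = sub$log2_fold_change,
                    adj_p = sub$adj_p, stringsAsFactors = FALSE)
  if (nrow(sub)) {
    gm_means <- grp_means(match(sub$gene_id, rownames(expr)))
    colnames(gm_means) <- paste0("mean_", unique(groups))
    out <- cbind(out, gm_means)
  } else {
    for (g in unique(groups)) out[[paste0("mean_", g)]] <- numeric()
  }
  for (d in distances) {
    out[[sprintf("has_peak_%dkb", d %/% 1000)]] <-
      if (nrow(sub)) gap <= d else logical()
  }
  rownames(out) <- NULL
  out
}
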