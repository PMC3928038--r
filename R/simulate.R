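## Synthetic study generator: genome, gene models, planted response
## elements, condition-labelled peak sets with partial overlap, and a
## two-group expression matrix. Every planted truth is recorded so each
## analysis stage has a known answer to recover.
##
## A single master seed feeds a named sub-stream per stage (genome,
## genes, peaks, plants, expression) so stages can be regenerated
## independently; identical configs give byte-identical bundles.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study the package's tests run: a 2 x
#' 1 Mb i.i.d. genome, 300 non-overlapping genes with exon structure, 400
#' peaks per condition of which 30% are shared between conditions
#' (hormone-independent), one DR4-type dyad planted 10x denser inside
#' peaks than outside, 40 induced / 20 repressed / 240 null genes with a
#' 1.5 log2 effect and 0.25 sd noise at 3 replicates per group, and half
#' of the induced genes given a motif-bearing peak within 25 kb of their
#' TSS (TSS-offsets drawn half-normal, sd 8 kb).
#'
#' @param seed master integer seed.
#' @param contigs named numeric vector of contig lengths.
#' @param base_composition probabilities for A, C, G, T (sum 1).
#' @param n_genes number of genes.
#' @param exon_count_range,exon_length_range,intron_length_range gene
#'   anatomy ranges (uniform draws).
#' @param motif_plants list of `list(notation=, bg_rate=, peak_rate=)`
#'   planted motifs with per-bp Poisson rates outside/inside peaks.
#' @param n_peaks peaks per condition.
#' @param peak_length_range peak width range in bp.
#' @param shared_peak_fraction fraction of each condition's peaks shared
#'   (identical) between conditions.
#' @param conditions two condition labels.
#' @param n_induced,n_repressed regulated gene counts (the rest are null).
#' @param effect_log2 planted log2 effect size.
#' @param noise_sd per-sample log2 noise sd.
#' @param replicates samples per group.
#' @param base_log2_mean,base_log2_sd baseline log2 intensity distribution.
#' @param proximal_tre_fraction fraction of induced genes given a
#'   motif-bearing peak near their TSS.
#' @param proximal_max_bp maximal TSS gap of those peaks.
#' @param proximal_sd_bp half-normal sd of the TSS gap.
#' @param peak_tss_exclusion_bp background peaks keep at least this gap to
#'   every gene TSS (0 disables; used for planted-construction tests).
#' @param gene_min_spacing_bp minimum gap enforced between transcripts at
#'   placement time (0 = only non-overlap). Set this above
#'   2 * peak_tss_exclusion_bp when peaks must associate with a single
#'   gene's TSS exclusively.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       contigs = c(chrA = 1e6, chrB = 1e6),
                       base_composition = c(A = .25, C = .25, G = .25, T = .25),
                       n_genes = 300,
                       exon_count_range = c(1, 8),
                       exon_length_range = c(100, 300),
                       intron_length_range = c(200, 1000),
                       motif_plants = list(list(notation = "AGGnCA-4-AGGnCA",
                                                bg_rate = 2e-5,
                                                peak_rate = 2e-4)),
                       n_peaks = 400,
                       peak_length_range = c(200, 500),
                       shared_peak_fraction = 0.3,
                       conditions = c("untreated", "T3"),
                       n_induced = 40, n_repressed = 20,
                       effect_log2 = 1.5, noise_sd = 0.25, replicates = 3,
                       base_log2_mean = 10, base_log2_sd = 1,
                       proximal_tre_fraction = 0.5,
                       proximal_max_bp = 25000, proximal_sd_bp = 8000,
                       peak_tss_exclusion_bp = 0,
                       gene_min_spacing_bp = 0) {
  stopifnot(abs(sum(base_composition) - 1) < 1e-8,
            all(base_composition >= 0),
            shared_peak_fraction >= 0, shared_peak_fraction <= 1,
            proximal_tre_fraction >= 0, proximal_tre_fraction <= 1,
            replicates >= 2, length(conditions) == 2,
            n_induced + n_repressed <= n_genes)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an i.i.d. genome
#' @param config a [sim_config()].
#' @return sequence set (named character vector).
#' @export
simulate_genome <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(config$seed, "genome"))
  bases <- names(config$base_composition)
  out <- vapply(config$contigs, function(len) {
    paste(sample(bases, len, replace = TRUE, prob = config$base_composition),
          collapse = "")
  }, "")
  names(out) <- names(config$contigs)
  out
}

## concretize an IUPAC notation into one DNA instance (degenerate
## positions drawn uniformly over the code's A/C/G/T subset)
concretize_motif <- function(motif) {
  if (is.character(motif)) motif <- parse_motif_notation(motif)
  pick <- function(word) {
    paste(vapply(strsplit(word, "")[[1]], function(cd) {
      s <- setdiff(IUPAC_SETS[[cd]], "N")
      if (length(s) == 1) s else sample(s, 1)
    }, ""), collapse = "")
  }
  if (inherits(motif, "iupac_pattern")) return(pick(motif$pattern))
  s <- if (motif$spacer_min == motif$spacer_max) motif$spacer_min else
    sample(motif$spacer_min:motif$spacer_max, 1)
  paste0(pick(motif$left),
         pick(paste(rep("N", s), collapse = "")),
         pick(motif$right))
}

## overwrite genome at (chrom, start) with an instance string
write_instance <- function(genome, chrom, start, instance) {
  substr(genome[[chrom]], start + 1, start + nchar(instance)) <- instance
  genome
}

#' Plant motif instances into a genome at a Poisson rate
#'
#' Instances (fresh random concretizations of the notation's degenerate
#' positions) are written at Poisson(rate x bp) uniformly drawn,
#' non-overlapping positions within `regions` (default: whole contigs).
#' No instance straddles a region or contig boundary.
#'
#' @param genome sequence set.
#' @param motif parsed motif or notation string.
#' @param rate expected instances per bp.
#' @param regions optional interval data.frame restricting placement.
#' @param avoid optional interval data.frame of positions plants must not
#'   overlap (e.g. earlier plants).
#' @param n_exact if not NULL, plant exactly this many instances instead of
#'   a Poisson draw.
#' @return list `genome` (modified) and `ledger` (data.frame
#'   `chrom, start, end, strand, notation, instance`).
#' @export
plant_motifs <- function(genome, motif, rate, regions = NULL, avoid = NULL,
                         n_exact = NULL) {
  if (is.character(motif)) motif <- parse_motif_notation(motif)
  if (is.null(regions)) regions <- whole_genome_regions(genome)
  regions <- merge_intervals(regions)
  total_bp <- sum(interval_width(regions))
  n <- if (is.null(n_exact)) stats::rpois(1, rate * total_bp) else n_exact
  ledger <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                       strand = character(), notation = character(),
                       instance = character(), stringsAsFactors = FALSE)
  if (n == 0) return(list(genome = genome, ledger = ledger))
  cum <- cumsum(interval_width(regions))
  occupied <- if (is.null(avoid)) ledger[c("chrom", "start", "end")] else
    avoid[c("chrom", "start", "end")]
  placed <- 0; tries <- 0
  while (placed < n) {
    tries <- tries + 1
    if (tries > 200 * n) {
      stopf("plant_motifs: cannot place %d instances in %d bp (capacity exceeded)",
            n, total_bp)
    }
    inst <- concretize_motif(motif)
    w <- nchar(inst)
    u <- floor(stats::runif(1) * total_bp)
    ri <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
    start <- regions$start[ri] + (u - c(0, cum)[ri])
    if (start + w > regions$end[ri]) next
    cn <- regions$chrom[ri]
    occ <- occupied[occupied$chrom == cn, , drop = FALSE]
    if (nrow(occ) && any(start < occ$end & start + w > occ$start)) next
    strand <- sample(c("+", "-"), 1)
    written <- if (strand == "+") inst else reverse_complement(inst)
    genome <- write_instance(genome, cn, start, written)
    row <- data.frame(chrom = cn, start = start, end = start + w,
                      strand = strand, notation = motif_notation(motif),
                      instance = written, stringsAsFactors = FALSE)
    ledger <- rbind(ledger, row)
    occupied <- rbind(occupied[c("chrom", "start", "end")],
                      row[c("chrom", "start", "end")])
    placed <- placed + 1
  }
  list(genome = genome, ledger = ledger)
}

## place n non-overlapping intervals of the given widths uniformly,
## optionally keeping a minimum gap to a set of excluded points (TSSs)
place_intervals <- function(contigs, widths, occupied = NULL,
                            exclude_points = NULL, exclude_bp = 0,
                            margin = 0, what = "interval") {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
  occ <- if (is.null(occupied)) out else occupied[c("chrom", "start", "end")]
  for (w in widths) {
    placed <- FALSE
    for (try in 1:500) {
      cn <- sample(names(contigs), 1, prob = contigs / sum(contigs))
      start <- floor(stats::runif(1) * (contigs[[cn]] - w))
      end <- start + w
      occ_c <- occ[occ$chrom == cn, , drop = FALSE]
      if (nrow(occ_c) && any(start - margin < occ_c$end &
                               end + margin > occ_c$start)) next
      if (!is.null(exclude_points) && exclude_bp > 0) {
        pts <- exclude_points[exclude_points$chrom == cn, , drop = FALSE]
        if (nrow(pts) && any(tss_peak_gap(pts$pos, start, end) <= exclude_bp)) next
      }
      row <- data.frame(chrom = cn, start = start, end = end,
                        stringsAsFactors = FALSE)
      out <- rbind(out, row)
      occ <- rbind(occ, row)
      placed <- TRUE
      break
    }
    if (!placed) stopf("rejection sampling failed placing a %d bp %s", w, what)
  }
  out
}

#' Simulate gene models and condition-labelled peak sets
#'
#' Genes are placed without transcript overlap. Each condition receives
#' `n_peaks` peaks: a shared block (identical intervals in both
#' conditions, `shared_peak_fraction` of each set) plus condition-unique
#' peaks. `proximal_tre_fraction` of induced genes get a shared peak whose
#' TSS gap is drawn half-normal (sd `proximal_sd_bp`, truncated at
#' `proximal_max_bp`); those peaks later receive a guaranteed planted
#' motif instance. Truth tables record gene classes and which gene got
#' which peak.
#'
#' @param genome sequence set.
#' @param config a [sim_config()].
#' @return list `gene_models`, `peak_sets` (named list of peak tables),
#'   `truth` (list with `gene_class`, `proximal`, `peak_origin`).
#' @export
simulate_genes_and_peaks <- function(genome, config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  clen <- stats::setNames(nchar(genome), names(genome))

  ## ---- genes ----
  set.seed(stage_seed(config$seed, "genes"))
  n <- config$n_genes
  anat <- lapply(seq_len(n), function(i) {
    k <- sample(config$exon_count_range[1]:config$exon_count_range[2], 1)
    ex <- round(stats::runif(k, config$exon_length_range[1],
                             config$exon_length_range[2]))
    intr <- if (k > 1) round(stats::runif(k - 1, config$intron_length_range[1],
                                          config$intron_length_range[2])) else numeric()
    list(ex = ex, intr = intr, len = sum(ex) + sum(intr))
  })
  pos <- place_intervals(clen, vapply(anat, `[[`, 0, "len"),
                         margin = config$gene_min_spacing_bp, what = "gene")
  gm <- data.frame(gene_id = sprintf("gene_%03d", seq_len(n)),
                   chrom = pos$chrom,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   tx_start = pos$start, tx_end = pos$end,
                   stringsAsFactors = FALSE)
  gm$exon_starts <- lapply(seq_len(n), function(i) {
    a <- anat[[i]]
    starts <- pos$start[i] + cumsum(c(0, utils::head(a$ex, -1) + a$intr))
    starts
  })
  gm$exon_ends <- lapply(seq_len(n), function(i) {
    gm$exon_starts[[i]] + anat[[i]]$ex
  })
  ## CDS: trim ~30% off the outermost exons as UTRs
  gm$cds_start <- vapply(seq_len(n), function(i) {
    e1 <- anat[[i]]$ex[1]
    gm$exon_starts[[i]][1] + max(1, round(0.3 * e1))
  }, 0)
  gm$cds_end <- vapply(seq_len(n), function(i) {
    ek <- anat[[i]]$ex[length(anat[[i]]$ex)]
    gm$exon_ends[[i]][length(anat[[i]]$ex)] - max(1, round(0.3 * ek))
  }, 0)
  bad <- gm$cds_start >= gm$cds_end  # tiny single-exon genes: make noncoding
  gm$cds_start[bad] <- gm$cds_end[bad] <- gm$tx_start[bad]
  gm$tss <- ifelse(gm$strand == "+", gm$tx_start, gm$tx_end - 1)

  ## gene classes
  cls <- rep("null", n)
  reg_idx <- sample(n, config$n_induced + config$n_repressed)
  cls[reg_idx[seq_len(config$n_induced)]] <- "induced"
  if (config$n_repressed > 0) {
    cls[reg_idx[config$n_induced + seq_len(config$n_repressed)]] <- "repressed"
  }
  gene_class <- data.frame(gene_id = gm$gene_id, class = cls,
                           stringsAsFactors = FALSE)

  ## ---- peaks ----
  set.seed(stage_seed(config$seed, "peaks"))
  n_shared <- round(config$shared_peak_fraction * config$n_peaks)
  induced <- which(cls == "induced")
  n_prox <- round(config$proximal_tre_fraction * length(induced))
  prox_genes <- if (n_prox > 0) sort(sample(induced, n_prox)) else integer()
  if (n_prox > n_shared) stopf("shared peak quota too small for proximal peaks")
  rw <- function(k) round(stats::runif(k, config$peak_length_range[1],
                                       config$peak_length_range[2]))
  tss_pts <- data.frame(chrom = gm$chrom, pos = gm$tss, stringsAsFactors = FALSE)
  prox <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     stringsAsFactors = FALSE)
  prox_truth <- data.frame(gene_id = character(), peak = character(),
                           gap = numeric(), stringsAsFactors = FALSE)
  for (gi in prox_genes) {
    w <- rw(1)
    for (try in 1:200) {
      gap <- min(config$proximal_max_bp,
                 round(abs(stats::rnorm(1, 0, config$proximal_sd_bp))))
      tss <- gm$tss[gi]; cn <- gm$chrom[gi]
      if (gap == 0) {
        start <- tss - floor(w / 2)
      } else if (stats::runif(1) < 0.5) {
        start <- tss - gap - w      # peak entirely 5' of the TSS coordinate
      } else {
        start <- tss + gap          # entirely 3'
      }
      if (start < 0 || start + w > clen[[cn]]) next
      if (nrow(prox) && any(prox$chrom == cn & start < prox$end &
                              start + w > prox$start)) next
      ## other genes must not accidentally gain a proximal peak when the
      ## construction promises exclusivity
      if (config$peak_tss_exclusion_bp > 0) {
        others <- tss_pts[-gi, , drop = FALSE]
        oc <- others[others$chrom == cn, , drop = FALSE]
        if (nrow(oc) && any(tss_peak_gap(oc$pos, start, start + w) <=
                              config$peak_tss_exclusion_bp)) next
      }
      prox <- rbind(prox, data.frame(chrom = cn, start = start, end = start + w,
                                     stringsAsFactors = FALSE))
      prox_truth <- rbind(prox_truth,
                          data.frame(gene_id = gm$gene_id[gi],
                                     peak = sprintf("shared_%03d", nrow(prox)),
                                     gap = gap, stringsAsFactors = FALSE))
      break
    }
  }
  if (nrow(prox) < n_prox) stopf("could not place all proximal peaks")
  excl_pts <- if (config$peak_tss_exclusion_bp > 0) tss_pts else NULL
  shared_bg <- place_intervals(clen, rw(n_shared - nrow(prox)), occupied = prox,
                               exclude_points = excl_pts,
                               exclude_bp = config$peak_tss_exclusion_bp,
                               what = "peak")
  shared <- rbind(prox, shared_bg)
  shared$name <- sprintf("shared_%03d", seq_len(nrow(shared)))
  n_uniq <- config$n_peaks - n_shared
  peak_sets <- list()
  origin <- list()
  for (cond in config$conditions) {
    uniq <- place_intervals(clen, rw(n_uniq), occupied = shared,
                            exclude_points = excl_pts,
                            exclude_bp = config$peak_tss_exclusion_bp,
                            what = "peak")
    if (nrow(uniq)) uniq$name <- sprintf("%s_%03d", cond, seq_len(nrow(uniq)))
    all <- rbind(shared, uniq)
    scores <- stats::rgamma(nrow(all), shape = 2, scale = 15)
    peak_sets[[cond]] <- peaks_table(all$chrom, all$start, all$end,
                                     score = scores, condition = cond,
                                     name = all$name)
    origin[[cond]] <- data.frame(name = all$name,
                                 origin = rep(c("shared", "unique"),
                                              c(nrow(shared), nrow(uniq))),
                                 stringsAsFactors = FALSE)
  }
  list(gene_models = gm, peak_sets = peak_sets,
       truth = list(gene_class = gene_class, proximal = prox_truth,
                    peak_origin = origin))
}

#' Simulate a raw expression matrix from planted gene classes
#'
#' Null genes draw raw intensities 2^(base + N(0, sd)); induced/repressed
#' genes shift the second group's mean by +/- `effect_log2` in log2 space.
#' Intensities are raw-scale, compatible with [normalize_expression()]'s
#' log2(x + offset) transform.
#'
#' @param config a [sim_config()].
#' @param gene_class truth data.frame (`gene_id`, `class`).
#' @return list `raw` (matrix genes x samples) and `groups` (label per
#'   column, first condition then second).
#' @export
simulate_expression <- function(config, gene_class) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(config$seed, "expression"))
  n <- nrow(gene_class); r <- config$replicates
  base <- stats::rnorm(n, config$base_log2_mean, config$base_log2_sd)
  eff <- ifelse(gene_class$class == "induced", config$effect_log2,
                ifelse(gene_class$class == "repressed", -config$effect_log2, 0))
  groups <- rep(config$conditions, each = r)
  mu <- outer(base, rep(0, 2 * r), "+") +
    outer(eff, as.numeric(groups == config$conditions[2]), "*")
  raw <- 2^(mu + matrix(stats::rnorm(n * 2 * r, 0, config$noise_sd), n))
  dimnames(raw) <- list(gene_class$gene_id,
                        paste0(groups, "_", rep(seq_len(r), 2)))
  list(raw = raw, groups = groups)
}

#' Simulate a complete study bundle
#'
#' Chains genome, gene/peak simulation, motif planting (background rate in
#' the genome outside peaks, in-peak rate inside the peak union, plus one
#' guaranteed instance centered in every proximal peak) and expression.
#' With `dir` given, writes FASTA, refFlat, per-condition BED, expression
#' TSV, group map, truth TSVs and a JSON manifest; re-running the same
#' config reproduces byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return list `config, genome, gene_models, peak_sets, raw_expression,
#'   groups, truth` (truth includes the motif-plant ledger), plus `files`
#'   when written.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  genome <- simulate_genome(config)
  gp <- simulate_genes_and_peaks(genome, config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(config$seed, "plants"))
  peak_union <- merge_intervals(do.call(rbind, lapply(gp$peak_sets, function(p)
    p[c("chrom", "start", "end")])))
  peak_union$strand <- "*"
  bg_regions <- setdiff_intervals(whole_genome_regions(genome), peak_union)
  ledgers <- list()
  ledger_iv <- function() {
    lv <- do.call(rbind, c(ledgers, list(NULL)))
    if (is.null(lv)) NULL else lv[c("chrom", "start", "end")]
  }
  ## guaranteed motif instance centered in every proximal peak (planted
  ## first so Poisson plants cannot overwrite them)
  if (nrow(gp$truth$proximal) && length(config$motif_plants)) {
    motif <- config$motif_plants[[1]]$notation
    prox_peaks <- gp$peak_sets[[2]]
    prox_peaks <- prox_peaks[match(gp$truth$proximal$peak, prox_peaks$name), ,
                             drop = FALSE]
    centers <- interval_midpoint(prox_peaks)
    for (i in seq_len(nrow(prox_peaks))) {
      inst <- concretize_motif(motif)
      start <- centers[i] - floor(nchar(inst) / 2)
      strand <- sample(c("+", "-"), 1)
      written <- if (strand == "+") inst else reverse_complement(inst)
      genome <- write_instance(genome, prox_peaks$chrom[i], start, written)
      ledgers[[length(ledgers) + 1]] <-
        data.frame(chrom = prox_peaks$chrom[i], start = start,
                   end = start + nchar(inst), strand = strand,
                   notation = motif, instance = written,
                   stringsAsFactors = FALSE)
    }
  }
  for (mp in config$motif_plants) {
    pb <- plant_motifs(genome, mp$notation, mp$bg_rate, regions = bg_regions,
                       avoid = ledger_iv())
    genome <- pb$genome
    ledgers[[length(ledgers) + 1]] <- pb$ledger
    pp <- plant_motifs(genome, mp$notation, mp$peak_rate, regions = peak_union,
                       avoid = ledger_iv())
    genome <- pp$genome
    ledgers[[length(ledgers) + 1]] <- pp$ledger
  }
  plant_ledger <- do.call(rbind, c(ledgers, list(NULL)))
  expr <- simulate_expression(config, gp$truth$gene_class)
  bundle <- list(config = config, genome = genome,
                 gene_models = gp$gene_models, peak_sets = gp$peak_sets,
                 raw_expression = expr$raw, groups = expr$groups,
                 truth = c(gp$truth, list(plants = plant_ledger)))
  if (!is.null(dir)) bundle$files <- write_study_bundle(bundle, dir)
  bundle
}

write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.refflat"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"))
  write_fasta(bundle$genome, files$genome)
  write_refflat(bundle$gene_models, files$genes)
  write_expression_tsv(bundle$raw_expression, files$expression)
  utils::write.table(data.frame(sample = colnames(bundle$raw_expression),
                                group = bundle$groups),
                     files$groups, sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in names(bundle$peak_sets)) {
    files[[paste0("peaks_", cond)]] <- file.path(dir, sprintf("peaks_%s.bed", cond))
    write_bed(bundle$peak_sets[[cond]], files[[paste0("peaks_", cond)]])
  }
  files$truth_gene_class <- file.path(dir, "truth_gene_class.tsv")
  write_tsv_report(bundle$truth$gene_class, files$truth_gene_class)
  files$truth_proximal <- file.path(dir, "truth_proximal.tsv")
  write_tsv_report(bundle$truth$proximal, files$truth_proximal)
  files$truth_plants <- file.path(dir, "truth_plants.tsv")
  write_tsv_report(bundle$truth$plants %||%
                     data.frame(chrom = character(), start = numeric(),
                                end = numeric(), strand = character(),
                                notation = character(), instance = character()),
                   files$truth_plants)
  cfg <- bundle$config; cfg$motif_plants <- lapply(cfg$motif_plants, as.list)
  manifest <- list(package = "trescan",
                   seed = bundle$config$seed,
                   config = cfg[setdiff(names(cfg), "conditions")],
                   conditions = bundle$config$conditions,
                   files = lapply(files, basename))
  files$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files
}
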