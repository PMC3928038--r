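## One-shot pipeline: simulate (or load) a study, scan the response-element
## grammar, compute enrichment, annotation, condition overlap, consensus
## and expression linkage, and write every report plus a JSON manifest.

#' Path of the bundled response-element grammar file
#'
#' Nine motifs: the canonical and degenerate half-sites, DR4 dyads, ER6,
#' IP0, IP1 and two putative negative-element sequences.
#'
#' @return file path inside the installed package.
#' @export
default_motif_grammar <- function() {
  system.file("extdata", "tre_motifs.tsv", package = "trescan", mustWork = TRUE)
}

#' Load a study bundle written by [simulate_study()]
#'
#' @param dir bundle directory.
#' @return list with `genome`, `gene_models`, `peak_sets`, `raw_expression`,
#'   `groups`.
#' @export
read_study_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  conds <- unlist(manifest$conditions)
  peak_sets <- lapply(conds, function(cond)
    read_bed(file.path(dir, sprintf("peaks_%s.bed", cond)), condition = cond))
  names(peak_sets) <- conds
  groups <- utils::read.table(file.path(dir, "groups.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  list(genome = read_fasta(file.path(dir, "genome.fa")),
       gene_models = read_refflat(file.path(dir, "genes.refflat")),
       peak_sets = peak_sets,
       raw_expression = read_expression_tsv(file.path(dir, "expression.tsv")),
       groups = groups$group)
}

#' Run the full analysis over a study
#'
#' Stages: motif occurrence/enrichment report over both peak-set
#' conditions; feature-class distribution and enrichment; TSS-relative
#' profile; condition overlap; consensus PFM/IUPAC from the top peaks;
#' expression normalization, regulated-gene calls, TSS-distance
#' association and the strong-regulation binding table.
#'
#' @param study a bundle from [simulate_study()] or [read_study_bundle()].
#' @param motifs motif list (default: the bundled grammar).
#' @param out_dir optional directory: writes one TSV per report plus a
#'   JSON manifest.
#' @param promoter_bp,downstream_bp feature-map extents.
#' @param top_n peaks used for consensus derivation.
#' @param consensus_seed seed pattern anchoring the consensus alignment.
#' @param flank5,flank3 consensus flanks around the seed.
#' @param distances TSS distance cutoffs in bp.
#' @param fold_cutoff,alpha regulated-gene call thresholds.
#' @param fold_floor strong-regulation fold floor.
#' @param min_overlap_frac condition-overlap reciprocal fraction.
#' @return list of results: `motif_report`, `feature_report`,
#'   `genome_fractions`, `tss_profile`, `overlap`, `pfm`, `consensus`,
#'   `calls`, `association`, `heatmap_table`, `normalized`.
#' @export
run_pipeline <- function(study, motifs = NULL, out_dir = NULL,
                         promoter_bp = 5000, downstream_bp = 5000,
                         top_n = 150, consensus_seed = "AGGnCA",
                         flank5 = 2, flank3 = 0,
                         distances = c(1000, 5000, 25000),
                         fold_cutoff = 1.7, alpha = 0.05, fold_floor = 2.5,
                         min_overlap_frac = 0) {
  if (is.null(motifs)) motifs <- read_motif_grammar(default_motif_grammar())
  genome <- study$genome
  peak_sets <- study$peak_sets
  gm <- study$gene_models
  clen <- stats::setNames(nchar(genome), names(genome))

  motif_report <- table1_report(peak_sets, genome, motifs)

  fmap <- feature_map(gm, clen, promoter_bp, downstream_bp)
  feature_report <- do.call(rbind, lapply(names(peak_sets), function(cond) {
    fe <- feature_enrichment(peak_sets[[cond]], fmap)
    cbind(condition = cond, fe, stringsAsFactors = FALSE)
  }))
  profile <- tss_profile(peak_sets[[length(peak_sets)]], gm)
  overlap <- condition_overlap(peak_sets[[1]], peak_sets[[2]],
                               min_overlap_frac = min_overlap_frac)

  top <- rank_peaks(peak_sets[[length(peak_sets)]], top_n)
  pfm <- build_pfm_from_seed(extract_sequences(top, genome), consensus_seed,
                             flank5 = flank5, flank3 = flank3)
  consensus <- pfm_to_iupac(pfm)

  normalized <- normalize_expression(study$raw_expression)
  conds <- unique(study$groups)
  calls <- differential_calls(normalized, study$groups, conds[1], conds[2],
                              fold_cutoff = fold_cutoff, alpha = alpha)
  assoc <- associate_peaks_to_genes(calls, gm, peak_sets[[length(peak_sets)]],
                                    distances = distances)
  heat <- regulation_binding_heatmap_table(calls, gm,
                                           peak_sets[[length(peak_sets)]],
                                           normalized, study$groups,
                                           fold_floor = fold_floor,
                                           alpha = alpha,
                                           distances = distances)
  res <- list(motif_report = motif_report, feature_report = feature_report,
              genome_fractions = genome_feature_fractions(fmap),
              tss_profile = profile, overlap = overlap,
              pfm = pfm, consensus = consensus, calls = calls,
              association = assoc, heatmap_table = heat,
              normalized = normalized)
  if (!is.null(out_dir)) res$files <- write_pipeline_reports(res, out_dir)
  res
}

write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  wr <- function(df, name) {
    files[[name]] <<- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_report(df, files[[name]])
  }
  wr(res$motif_report, "motif_enrichment")
  wr(res$feature_report, "feature_enrichment")
  wr(data.frame(class = names(res$genome_fractions),
                fraction = as.numeric(res$genome_fractions)), "genome_fractions")
  wr(res$tss_profile, "tss_profile")
  wr(data.frame(a_only = res$overlap$a_only, shared_a = res$overlap$shared_a,
                shared_b = res$overlap$shared_b, b_only = res$overlap$b_only,
                fraction_shared = res$overlap$fraction_shared), "condition_overlap")
  wr(res$calls, "regulation_calls")
  wr(res$association, "tss_association")
  wr(res$heatmap_table, "strong_regulation_binding")
  files$consensus_pfm <- file.path(out_dir, "consensus_pfm.txt")
  write_pfm_jaspar(res$pfm, files$consensus_pfm,
                   name = paste0("consensus_", res$consensus$pattern))
  files$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(package = "trescan",
                            consensus = res$consensus$pattern,
                            files = lapply(files, basename)),
                       files$manifest, auto_unbox = TRUE, pretty = TRUE)
  files
}
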