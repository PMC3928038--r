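# Feature-class maps, peak classification, genome fractions, TSS
# profiles, condition overlap.


test_that("peak midpoint classification follows the precedence rules", {
  gm <- toy_genes()
  clen <- c(c1 = 10000, c2 = 8000)
  fmap <- feature_map(gm, clen, promoter_bp = 1000, downstream_bp = 1000)
  # 500 bp upstream of gA's + strand TSS (2000): promoter
  expect_equal(as.character(classify_peaks(peaks_table("c1", 1400, 1600), fmap)),
               "promoter")
  # inside gA's first intron (2300..2600)
  expect_equal(as.character(classify_peaks(peaks_table("c1", 2400, 2500), fmap)),
               "intron")
  # upstream of - strand gB means beyond tx_end 7500
  expect_equal(as.character(classify_peaks(peaks_table("c1", 7600, 7700), fmap)),
               "promoter")
  # past gB's tx_start on the - strand: downstream
  expect_equal(as.character(classify_peaks(peaks_table("c1", 5200, 5400), fmap)),
               "downstream")
  # far from everything
  expect_equal(as.character(classify_peaks(peaks_table("c1", 9500, 9700), fmap)),
               "intergenic")
  # contig with no genes at all
  fmap0 <- feature_map(gm[0, ], clen)
  expect_equal(as.character(classify_peaks(peaks_table("c2", 100, 200), fmap0)),
               "intergenic")
})

test_that("toy genome fractions follow from the construction", {
  # 10 kb contig, one + strand single-exon gene [4000,5000), fully coding,
  # 1 kb promoter and downstream: exon 10%, promoter 10%, downstream 10%,
  # intergenic 70%
  gm <- data.frame(gene_id = "g", chrom = "c1", strand = "+",
                   tx_start = 4000, tx_end = 5000,
                   cds_start = 4000, cds_end = 5000, stringsAsFactors = FALSE)
  gm$exon_starts <- list(4000); gm$exon_ends <- list(5000)
  gm$tss <- 4000
  fmap <- feature_map(gm, c(c1 = 10000), promoter_bp = 1000, downstream_bp = 1000)
  fr <- genome_feature_fractions(fmap)
  expect_equal(unname(fr[c("promoter", "exon", "downstream", "intergenic")]),
               c(.1, .1, .1, .7))
  expect_equal(unname(fr[c("five_utr", "three_utr", "intron")]), c(0, 0, 0))
  expect_equal(sum(fr), 1)

  # no genes at all
  fr0 <- genome_feature_fractions(feature_map(gm[0, ], c(c1 = 10000)))
  expect_equal(unname(fr0["intergenic"]), 1)
})

test_that("genome fractions and peak classes equal the per-base oracle", {
  set.seed(13)
  cfg <- sim_config(seed = 5, contigs = c(s1 = 60000, s2 = 40000),
                    n_genes = 12, n_peaks = 0, n_induced = 0, n_repressed = 0,
                    proximal_tre_fraction = 0, motif_plants = list())
  genome <- simulate_genome(cfg)
  gp <- simulate_genes_and_peaks(genome, cfg)
  gm <- gp$gene_models
  clen <- c(s1 = 60000, s2 = 40000)
  fmap <- feature_map(gm, clen, promoter_bp = 2000, downstream_bp = 2000)

  labs <- c(oracle_base_labels(gm, clen, "s1", 2000, 2000),
            oracle_base_labels(gm, clen, "s2", 2000, 2000))
  want <- table(factor(labs, levels = trescan:::FEATURE_CLASSES)) / sum(clen)
  got <- genome_feature_fractions(fmap)
  expect_equal(unname(got), as.numeric(want))
  expect_equal(sum(got), 1)

  # 1000 random peak midpoints agree with the per-base labels
  n <- 1000
  chrom <- sample(names(clen), n, TRUE)
  start <- floor(runif(n) * (clen[chrom] - 100))
  peaks <- peaks_table(chrom, start, start + 100)
  cls <- classify_peaks(peaks, fmap)
  mid <- floor((peaks$start + peaks$end) / 2)
  off <- c(s1 = 0, s2 = 60000)
  expect_equal(as.character(cls), labs[off[peaks$chrom] + mid + 1])
})

test_that("feature enrichment is the ratio of class shares", {
  gm <- data.frame(gene_id = "g", chrom = "c1", strand = "+",
                   tx_start = 4000, tx_end = 5000,
                   cds_start = 4000, cds_end = 5000, stringsAsFactors = FALSE)
  gm$exon_starts <- list(4000); gm$exon_ends <- list(5000)
  gm$tss <- 4000
  fmap <- feature_map(gm, c(c1 = 10000), promoter_bp = 1000, downstream_bp = 1000)
  # 2 of 4 peaks in the promoter (10% of genome): fold 0.5/0.1 = 5
  peaks <- peaks_table("c1", c(3200, 3500, 8000, 9000),
                       c(3300, 3600, 8100, 9100))
  fe <- feature_enrichment(peaks, fmap)
  expect_equal(fe$fold[fe$class == "promoter"], 5)
  expect_equal(sum(fe$pct_peaks), 100)
  expect_equal(sum(fe$pct_genome), 100, tolerance = 1e-9)
  # all peaks in one class: fold = 1 / genome share, zero elsewhere
  pk <- peaks_table("c1", c(3200, 3500), c(3300, 3600))
  fe2 <- feature_enrichment(pk, fmap)
  expect_equal(fe2$fold[fe2$class == "promoter"], 1 / 0.1)
  expect_equal(sum(fe2$n_peaks), 2)
})

test_that("null peak placement gives folds near 1", {
  set.seed(17)
  cfg <- sim_config(seed = 11, contigs = c(s1 = 2e5), n_genes = 15,
                    n_peaks = 0, n_induced = 0, n_repressed = 0,
                    proximal_tre_fraction = 0, motif_plants = list())
  genome <- simulate_genome(cfg)
  gm <- simulate_genes_and_peaks(genome, cfg)$gene_models
  fmap <- feature_map(gm, c(s1 = 2e5))
  # peaks proportional to genome composition = uniform midpoints
  n <- 4000
  start <- floor(runif(n) * (2e5 - 10))
  fe <- feature_enrichment(peaks_table("s1", start, start + 10), fmap)
  fr <- genome_feature_fractions(fmap)
  for (cls in names(fr)[fr > 0.03]) {
    se <- sqrt(fr[cls] * (1 - fr[cls]) / n) / fr[cls]
    expect_lt(abs(fe$fold[fe$class == cls] - 1), 4 * se)
  }
})

test_that("feature folds are invariant under genome duplication", {
  gm <- toy_genes()
  clen <- c(c1 = 10000, c2 = 8000)
  peaks <- peaks_table(c("c1", "c1", "c2"), c(1500, 2400, 500),
                       c(1700, 2600, 700))
  f1 <- feature_enrichment(peaks, feature_map(gm, clen, 1000, 1000))
  gm2 <- gm
  gm2$chrom <- paste0(gm2$chrom, "x")
  gmd <- rbind(gm, gm2)
  clend <- c(clen, c1x = 10000, c2x = 8000)
  f2 <- feature_enrichment(peaks, feature_map(gmd, clend, 1000, 1000))
  expect_equal(f1$fold, f2$fold)
})

test_that("TSS profile is orientation-corrected and centered on planted peaks", {
  gm <- toy_genes()
  # peak centered exactly on gA TSS (2000)
  p0 <- peaks_table("c1", 1950, 2050)
  pr <- tss_profile(p0, gm, W = 1000, bin = 100)
  expect_equal(sum(pr$count), 1)
  expect_equal(pr$bin_start[pr$count == 1], 0)
  # peak 300 bp 5' of gB (- strand, TSS 7499): midpoint at 7799 -> -300
  p1 <- peaks_table("c1", 7749, 7849)
  pr1 <- tss_profile(p1, gm, W = 1000, bin = 100)
  expect_equal(pr1$bin_start[pr1$count == 1], -300)
  # peaks beyond W are dropped
  p2 <- peaks_table("c1", 9800, 9900)
  expect_equal(sum(tss_profile(p2, gm, W = 1000, bin = 100)$count), 0)

  # planted Normal(0, 500) midpoint offsets recover mean about 0
  set.seed(19)
  n <- 2000
  offs <- round(rnorm(n, 0, 500))
  tssv <- rep(5000, n)
  pk <- peaks_table("cX", 5000 + offs - 50, 5000 + offs + 50)
  gmx <- data.frame(gene_id = "gx", chrom = "cX", strand = "+",
                    tx_start = 5000, tx_end = 6000, cds_start = 5000,
                    cds_end = 6000, stringsAsFactors = FALSE)
  gmx$exon_starts <- list(5000); gmx$exon_ends <- list(6000); gmx$tss <- 5000
  prx <- tss_profile(pk, gmx, W = 4000, bin = 100)
  m <- sum(prx$bin_center * prx$count) / sum(prx$count)
  expect_lt(abs(m), 3 * 500 / sqrt(n) + 50)  # 3 SE plus half-bin slack
})

test_that("condition overlap counts planted sharing correctly", {
  a <- peaks_table("c1", c(100, 500, 900), c(200, 600, 1000), condition = "a")
  expect_equal(condition_overlap(a, a)$fraction_shared, 1)

  b <- peaks_table("c2", c(100, 500), c(200, 600), condition = "b")
  ov <- condition_overlap(a, b)
  expect_equal(ov$fraction_shared, 0)
  expect_equal(ov$a_only, 3)
  expect_equal(ov$b_only, 2)

  # partial overlap with reciprocal fraction threshold
  x <- peaks_table("c1", 100, 200)
  y <- peaks_table("c1", 190, 290)  # 10 bp overlap = 10% of each
  expect_equal(condition_overlap(x, y)$fraction_shared, 1)
  expect_equal(condition_overlap(x, y, min_overlap_frac = 0.5)$fraction_shared, 0)
})

test_that("planted shared fractions are recovered across many peaks", {
  set.seed(23)
  n <- 500
  shared_frac <- 0.4
  n_shared <- n * shared_frac
  starts <- sort(sample(seq(1000, 4e6, by = 1200), n * 2 - n_shared))
  idx <- sample(seq_along(starts))
  sh <- starts[idx[seq_len(n_shared)]]
  ua <- starts[idx[(n_shared + 1):n]]
  ub <- starts[idx[(n + 1):(2 * n - n_shared)]]
  a <- peaks_table("c1", c(sh, ua), c(sh, ua) + 300, condition = "a")
  b <- peaks_table("c1", c(sh, ub), c(sh, ub) + 300, condition = "b")
  ov <- condition_overlap(a, b)
  se <- sqrt(shared_frac * (1 - shared_frac) / (2 * n))
  expect_lt(abs(ov$fraction_shared - shared_frac), 3 * se + 1e-9)
  expect_equal(ov$shared_a, ov$shared_b)  # symmetric with >=1 bp criterion
})
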