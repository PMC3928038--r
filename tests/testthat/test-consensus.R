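# Peak ranking, seeded PFM building, IUPAC consensus, PWM scanning.

test_that("rank_peaks orders by score with deterministic tie-breaks", {
  p <- peaks_table(c("c1", "c1", "c1"), c(10, 50, 30), c(20, 60, 40),
                   score = c(3, 1, 2))
  top <- rank_peaks(p, 2)
  expect_equal(top$score, c(3, 2))

  # ties broken by (chrom, start): stable across repeated calls
  pt <- peaks_table(c("c2", "c1", "c1"), c(5, 9, 2), c(15, 19, 12),
                    score = c(7, 7, 7))
  t1 <- rank_peaks(pt, 3); t2 <- rank_peaks(pt, 3)
  expect_identical(t1, t2)
  expect_equal(t1$chrom, c("c1", "c1", "c2"))
  expect_equal(t1$start, c(2, 9, 5))

  expect_warning(more <- rank_peaks(p, 10), "only 3")
  expect_equal(nrow(more), 3)
})

test_that("top-n peak scores dominate the rest", {
  set.seed(8)
  p <- peaks_table("c1", seq(0, 990, 10), seq(5, 995, 10),
                   score = runif(100, 0, 50))
  top <- rank_peaks(p, 20)
  expect_true(min(top$score) >= sort(p$score, decreasing = TRUE)[21])
})

test_that("seeded PFM on TGAGGTCA-bearing sequences recovers the consensus", {
  set.seed(91)
  seqs <- vapply(1:10, function(i) {
    left <- random_dna(20); right <- random_dna(20)
    paste0(left, "TGAGGTCA", right)
  }, "")
  # ensure flanks don't accidentally contain a closer seed match
  pfm <- build_pfm_from_seed(seqs, "AGGnCA", flank5 = 2, flank3 = 0)
  expect_equal(pfm$width, 8)
  expect_equal(pfm$n_sequences, 10)
  expect_equal(unname(colSums(pfm$counts)), rep(10, 8))
  cons <- pfm_to_iupac(pfm)
  expect_equal(cons$pattern, "TGAGGTCA")
})

test_that("PFM building is invariant to reverse-complementing every input", {
  set.seed(92)
  seqs <- vapply(1:20, function(i)
    paste0(random_dna(15), "CCTGAGGTCAAT", random_dna(15)), "")
  p1 <- build_pfm_from_seed(seqs, "AGGnCA", flank5 = 3, flank3 = 2)
  p2 <- build_pfm_from_seed(reverse_complement(seqs), "AGGnCA",
                            flank5 = 3, flank3 = 2)
  expect_equal(p1$counts, p2$counts)
})

test_that("all-identical windows give fully concentrated columns", {
  seqs <- rep("AAAAAGGTCAAAAA", 7)
  pfm <- build_pfm_from_seed(seqs, "AGGTCA", flank5 = 1, flank3 = 1)
  expect_true(all(apply(pfm$counts, 2, max) == 7))
  expect_error(build_pfm_from_seed(c("CCCCCC", "GGGGGG"), "AGGTCA"),
               "no usable seed matches")
})

test_that("sampling from a known PFM recovers column frequencies", {
  # truth: TGAGGTCA with the GG core and the C fixed (they anchor the
  # seed alignment deterministically), the other five columns 0.7 major /
  # 0.1 each minor
  set.seed(93)
  truth <- matrix(0.1, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  major <- strsplit("TGAGGTCA", "")[[1]]
  for (j in 1:8) truth[major[j], j] <- 0.7
  for (j in c(4, 5, 7)) {
    truth[, j] <- 0
    truth[major[j], j] <- 1
  }
  draw_window <- function() {
    paste(vapply(1:8, function(j)
      sample(rownames(truth), 1, prob = truth[, j]), ""), collapse = "")
  }
  recover <- function(ndraw) {
    seqs <- vapply(seq_len(ndraw), function(i)
      paste0("CC", draw_window(), "CC"), "")
    pfm <- build_pfm_from_seed(seqs, "nnnGGnCn", flank5 = 0, flank3 = 0)
    sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  }
  # 200 draws: every free-column frequency within 4 binomial SE of truth
  freq <- recover(200)
  for (j in setdiff(1:8, c(4, 5, 7))) {
    se <- sqrt(truth[, j] * (1 - truth[, j]) / 200)
    expect_true(all(abs(freq[, j] - truth[, j]) < 4 * pmax(se, 1e-3)),
                info = sprintf("column %d", j))
  }
  # KL divergence to truth decreases toward zero with sample size
  kl_of <- function(freq) {
    mean(vapply(setdiff(1:8, c(4, 5, 7)), function(j) {
      p <- truth[, j]; q <- pmax(freq[, j], 1e-9)
      sum(p * log(p / q))
    }, 0))
  }
  kl <- vapply(c(100, 400, 1600), function(n) kl_of(recover(n)), 0)
  expect_true(kl[3] < kl[1])
  expect_lt(kl[3], 0.02)
})

test_that("IUPAC consensus rule: major base, else smallest covering code", {
  mk <- function(freqs) {
    counts <- round(freqs * 100)
    structure(list(counts = matrix(counts, 4, 1,
                                   dimnames = list(c("A", "C", "G", "T"), NULL)),
                   n_sequences = 100, width = 1), class = "pfm")
  }
  expect_equal(pfm_to_iupac(mk(c(1, 0, 0, 0)))$pattern, "A")
  expect_equal(pfm_to_iupac(mk(c(.5, .05, .45, 0)))$pattern, "R")
  expect_equal(pfm_to_iupac(mk(c(.4, .3, .3, 0)))$pattern, "V")
  expect_equal(pfm_to_iupac(mk(c(.25, .25, .25, .25)))$pattern, "N")
  expect_equal(pfm_to_iupac(mk(c(.65, .35, 0, 0)))$pattern, "A")
})

test_that("PWM log-odds follow the stated formula and consensus maximizes", {
  counts <- matrix(c(10, 0, 0, 0,
                     0, 0, 10, 0), 4, 2,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm <- structure(list(counts = counts, n_sequences = 10, width = 2),
                   class = "pfm")
  pwm <- pfm_to_pwm(pfm, pseudocount = 1)
  # formula check at one cell: count 10, bg 0.25, n 10, pseudocount 1
  expect_equal(unname(pwm$logodds["A", 1]),
               log2(((10 + 1 * 0.25) / (10 + 1)) / 0.25))
  expect_equal(pwm$max_score, sum(apply(pwm$logodds, 2, max)))
  hits <- pwm_scan("AG", pwm, score_fraction = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, pwm$max_score)
})

test_that("a uniform PFM scores every window zero", {
  counts <- matrix(25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm <- structure(list(counts = counts, n_sequences = 100, width = 3),
                   class = "pfm")
  pwm <- pfm_to_pwm(pfm, pseudocount = 1)
  expect_true(all(abs(pwm$logodds) < 1e-12))
  expect_equal(pwm$max_score, 0)
})

test_that("pwm_scan equals an exhaustive window-scoring oracle", {
  set.seed(94)
  seqs <- vapply(1:60, function(i) paste0(random_dna(6), "TGAGGTCA",
                                          random_dna(6)), "")
  pfm <- build_pfm_from_seed(seqs, "AGGnCA", flank5 = 2, flank3 = 0)
  pwm <- pfm_to_pwm(pfm)
  seq <- random_dna(2000)
  # plant instances on both strands so the hit set is non-empty
  substr(seq, 301, 308) <- "TGAGGTCA"
  substr(seq, 901, 908) <- reverse_complement("TGAGGTCA")
  frac <- 0.7
  got <- pwm_scan(seq, pwm, score_fraction = frac)
  expect_gte(nrow(got), 2)
  # oracle: score every window on both strands from the matrix directly
  chars <- strsplit(seq, "")[[1]]
  L <- pwm$width
  want <- list()
  for (i in 0:(length(chars) - L)) {
    win <- chars[(i + 1):(i + L)]
    sc_f <- sum(vapply(1:L, function(j) pwm$logodds[win[j], j], 0))
    rcw <- rev(c(A = "T", C = "G", G = "C", T = "A")[win])
    sc_r <- sum(vapply(1:L, function(j) pwm$logodds[rcw[j], j], 0))
    if (sc_f >= frac * pwm$max_score) {
      want[[length(want) + 1]] <- data.frame(start = i, strand = "+", score = sc_f)
    }
    if (sc_r >= frac * pwm$max_score) {
      want[[length(want) + 1]] <- data.frame(start = i, strand = "-", score = sc_r)
    }
  }
  want <- do.call(rbind, want)
  got <- got[order(got$start, got$strand), ]
  want <- want[order(want$start, want$strand), ]
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$score, want$score)
})

test_that("pwm_scan hit sets shrink as the score fraction rises", {
  set.seed(95)
  seqs <- vapply(1:40, function(i) paste0(random_dna(4), "TGAGGTCA",
                                          random_dna(4)), "")
  pfm <- build_pfm_from_seed(seqs, "AGGnCA", flank5 = 2, flank3 = 0)
  pwm <- pfm_to_pwm(pfm)
  seq <- random_dna(5000)
  ns <- vapply(c(0.5, 0.7, 0.9, 1), function(f)
    nrow(pwm_scan(seq, pwm, score_fraction = f)), 0)
  expect_true(all(diff(ns) <= 0))
  expect_equal(nrow(pwm_scan("ACG", pwm)), 0)  # shorter than the PWM
})

test_that("JASPAR-style PFM text round-trips", {
  set.seed(96)
  seqs <- vapply(1:15, function(i) paste0(random_dna(3), "TGAGGTCA",
                                          random_dna(3)), "")
  pfm <- build_pfm_from_seed(seqs, "AGGnCA", flank5 = 2, flank3 = 0)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pfm_jaspar(pfm, f, name = "halfsite")
  pfm2 <- read_pfm_jaspar(f)
  expect_equal(pfm2$counts, pfm$counts, ignore_attr = TRUE)
  expect_equal(pfm2$width, pfm$width)
})
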