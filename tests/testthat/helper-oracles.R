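# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's scanning/statistics code paths: matching
# is per-position set membership, stats are recomputed from first
# principles.

# base sets per IUPAC code under the package's N rule (`N` code matches N;
# specific codes do not)
oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

oracle_rc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# does word (IUPAC) match seq chars at 0-based offset i?
oracle_word_at <- function(chars, word_chars, i) {
  if (i + length(word_chars) > length(chars)) return(FALSE)
  for (j in seq_along(word_chars)) {
    if (!(chars[i + j] %in% oracle_sets[[word_chars[j]]])) return(FALSE)
  }
  TRUE
}

# all matches of a plain IUPAC pattern, both strands, palindromes once
oracle_scan_pattern <- function(seq, pattern) {
  seq <- toupper(seq); pattern <- toupper(pattern)
  chars <- strsplit(seq, "")[[1]]
  w <- nchar(pattern)
  pats <- list(c("+", pattern))
  rc <- oracle_rc(pattern)
  if (rc != pattern) pats <- c(pats, list(c("-", rc)))
  out <- list()
  for (p in pats) {
    wc <- strsplit(p[2], "")[[1]]
    for (i in 0:(max(0, length(chars) - w))) {
      if (length(chars) >= w && oracle_word_at(chars, wc, i)) {
        out[[length(out) + 1]] <- data.frame(start = i, end = i + w,
                                             strand = p[1],
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  do.call(rbind, out)
}

# all dyad matches as (start, spacer, strand) triples
oracle_scan_dyad <- function(seq, left, smin, smax, right) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  lw <- strsplit(toupper(left), "")[[1]]
  rw <- strsplit(toupper(right), "")[[1]]
  rc_l <- strsplit(oracle_rc(left), "")[[1]]
  rc_r <- strsplit(oracle_rc(right), "")[[1]]
  palindromic <- identical(oracle_rc(right), toupper(left)) &&
    identical(oracle_rc(left), toupper(right))
  out <- list()
  for (s in smin:smax) {
    w <- length(lw) + s + length(rw)
    if (length(chars) < w) next
    for (i in 0:(length(chars) - w)) {
      if (oracle_word_at(chars, lw, i) &&
          oracle_word_at(chars, rw, i + length(lw) + s)) {
        out[[length(out) + 1]] <- data.frame(start = i, spacer = s, strand = "+")
      }
      if (!palindromic &&
          oracle_word_at(chars, rc_r, i) &&
          oracle_word_at(chars, rc_l, i + length(rc_r) + s)) {
        out[[length(out) + 1]] <- data.frame(start = i, spacer = s, strand = "-")
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), spacer = integer(),
                                      strand = character()))
  do.call(rbind, out)
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

random_dna <- function(n, p = c(.25, .25, .25, .25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

random_iupac <- function(len, codes = names(oracle_sets)) {
  paste(sample(codes, len, replace = TRUE,
               prob = c(rep(4, 4), rep(1, 11))), collapse = "")
}

# tiny deterministic genome + annotation fixture used across tests
toy_genome <- function() {
  set.seed(42)
  c(c1 = random_dna(10000), c2 = random_dna(8000))
}

toy_genes <- function() {
  gm <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("c1", "c1", "c2"),
    strand = c("+", "-", "+"),
    tx_start = c(2000, 6000, 1000),
    tx_end = c(3000, 7500, 4000),
    cds_start = c(2100, 6200, 1500),
    cds_end = c(2900, 7300, 3500),
    stringsAsFactors = FALSE)
  gm$exon_starts <- list(c(2000, 2600), c(6000, 7000), c(1000, 2000, 3000))
  gm$exon_ends <- list(c(2300, 3000), c(6500, 7500), c(1600, 2400, 4000))
  gm$tss <- ifelse(gm$strand == "+", gm$tx_start, gm$tx_end - 1)
  gm
}

# independent per-base oracle: label every base of a contig by walking the
# gene models directly
oracle_base_labels <- function(gm, clen, chrom, promoter_bp = 5000,
                               downstream_bp = 5000) {
  lab <- rep("intergenic", clen[[chrom]])
  paint <- function(lab, s, e, cls) {
    s <- max(0, s); e <- min(length(lab), e)
    if (s >= e) return(lab)
    idx <- (s + 1):e
    free <- lab[idx] == "intergenic"
    lab[idx[free]] <- cls
    lab
  }
  g <- gm[gm$chrom == chrom, , drop = FALSE]
  for (cls in c("promoter", "five_utr", "three_utr", "exon", "intron",
                "downstream")) {
    for (i in seq_len(nrow(g))) {
      plus <- g$strand[i] == "+"
      if (cls == "promoter") {
        if (plus) lab <- paint(lab, g$tx_start[i] - promoter_bp, g$tx_start[i], cls)
        else lab <- paint(lab, g$tx_end[i], g$tx_end[i] + promoter_bp, cls)
      } else if (cls == "downstream") {
        if (plus) lab <- paint(lab, g$tx_end[i], g$tx_end[i] + downstream_bp, cls)
        else lab <- paint(lab, g$tx_start[i] - downstream_bp, g$tx_start[i], cls)
      } else if (cls == "intron") {
        lab <- paint(lab, g$tx_start[i], g$tx_end[i], cls)
      } else {
        es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
        cs <- g$cds_start[i]; ce <- g$cds_end[i]
        noncoding <- cs == ce
        for (k in seq_along(es)) {
          if (cls == "exon") {
            if (noncoding) lab <- paint(lab, es[k], ee[k], cls)
            else lab <- paint(lab, max(es[k], cs), min(ee[k], ce), cls)
          } else if (!noncoding) {
            left <- c(es[k], min(ee[k], cs))   # exonic part 5' of CDS (+)
            right <- c(max(es[k], ce), ee[k])  # exonic part 3' of CDS (+)
            if (cls == "five_utr") {
              seg <- if (plus) left else right
            } else {
              seg <- if (plus) right else left
            }
            if (seg[1] < seg[2]) lab <- paint(lab, seg[1], seg[2], cls)
          }
        }
      }
    }
  }
  lab
}
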