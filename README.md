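# trescan

Genome-wide analysis of thyroid hormone receptor (TRβ) ChIP binding peaks:
response-element grammar scanning, motif enrichment, genomic-context
annotation, consensus derivation, and linkage of binding events to
hormone-regulated gene classes.

## The problem

Thyroid hormone receptors activate and repress transcription through
response elements (TREs) built from AGGTCA-like half-sites arranged as
direct, everted or inverted repeats with characteristic spacers (DR-n,
ER-n, IP-n). Given ChIP peak sets called under two hormone conditions, a
genome, gene models and an expression matrix, the questions this package
answers are:

* how often do half-sites and dyad elements occur inside bound regions,
  and how enriched are they over their genomic representation?
* where do peaks fall relative to gene anatomy (promoter, UTRs, exons,
  introns, downstream, intergenic) and the transcription start site?
* what consensus emerges from the strongest peaks?
* which gene classes (hormone-induced, repressed, unaffected) carry a
  peak within 1/5/25 kb of their TSS?

## Core computations

* **Dyad grammar scanner** — motifs are written `HALF`, `HALF-k-HALF` or
  `HALF-a..b-HALF` over the IUPAC alphabet (e.g. `AGGnCA-4-AGGnCA` for a
  DR4 element). Scanning is bidirectional and reports every overlapping
  occurrence; a self-reverse-complementary footprint counts once. The
  pattern code `n` matches the unknown base N; specific codes do not.
* **Length-normalized enrichment** — for a motif m, region set R and
  background B, fold enrichment is
  `(hits_R / bp_R) / (hits_B / bp_B)`,
  with bidirectional hit counts; the fraction of regions containing ≥ 1
  hit is reported alongside. A permutation z-score
  `z = (obs − mean_null) / sd_null` tests co-localization of a motif with
  peaks against length-matched random placements.
* **Consensus** — one seed match per top-ranked peak (closest to the peak
  midpoint, reverse-complemented into seed orientation) is extended by
  fixed flanks and stacked into a position frequency matrix; an IUPAC
  consensus is read off per column (single base at ≥ 0.6 frequency, else
  the smallest code covering ≥ 0.8), and a log-odds PWM
  `log2((c_b + p·bg_b) / (n + p) / bg_b)` supports threshold scanning.
* **Feature annotation** — a single precedence-resolved feature map
  (promoter > 5′UTR > 3′UTR > exon > intron > downstream > intergenic,
  promoter = 5 kb upstream of the TSS) classifies peak midpoints and
  yields per-class genome fractions from the same intervals, so
  `fold = peak share / genome share` is internally consistent.
* **Expression linkage** — intensities are normalized by
  `log2(x + 50)` + quantile normalization; regulated genes are called by
  moderated t-statistics with Benjamini–Hochberg adjustment at
  |fold| ≥ 1.7 and adjusted p < 0.05; each gene class is then scored for
  peaks within 1, 5 and 25 kb of the TSS.
* **Synthetic studies** — a seeded generator emits a genome, gene models,
  condition-labelled peak sets with a planted shared fraction, motifs
  planted at controlled rates inside and outside peaks, and a two-group
  expression matrix with planted effects, so every stage of the analysis
  has a recoverable truth.

## Worked example

```r
library(trescan)

study <- simulate_study(sim_config(seed = 1))
res <- run_pipeline(study, out_dir = "reports")

subset(res$motif_report, condition == "T3",
       c(motif_label, pct_regions_with_hit, fold_enrichment))
#>     motif_label pct_regions_with_hit fold_enrichment
#> 2      Halfsite                18.75       1.1397067
#> 4  Halfsite_deg                54.75       1.2148567
#> 6           DR4                 9.75       5.8091845
#> 8       DR4_deg                11.50       4.3170707
#> 10          ER6                 1.25       1.2073164
#> 12          IP0                 1.00       0.8766974
#> 14          IP1                 0.75       0.7368793
#> 16         Neg1                14.75       1.0844446
#> 18         Neg2                 0.00              NA

res$overlap$fraction_shared
#> [1] 0.38

table(res$calls$call)
#>   induced repressed unchanged
#>        38        20       242
```

Reading the output: the planted DR4 dyad (`AGGnCA-4-AGGnCA`, placed ten
times denser inside peaks than outside) shows ~6-fold enrichment against
the whole-genome background — the whole-genome denominator includes the
enriched peaks themselves, which at this desk scale are a non-negligible
genome fraction; `fold_enrichment(..., exclude_foreground = TRUE)`
recovers the planted 10:1 rate ratio. Unplanted dyads (ER6, IP0, IP1) sit
at fold ≈ 1, and half-site percentages match what uniform i.i.d. sequence
plus planted elements predict. Of the 40 + 20 planted regulated genes, 38
and 20 are recalled at the 1.7-fold / adjusted-p 0.05 thresholds. The
shared-peak fraction (0.38 at ≥ 1 bp overlap) sits above the planted 0.30
because desk-scale peak density adds chance overlaps; a reciprocal-overlap
threshold isolates the planted sharing.

Every report is also written as TSV under `reports/` together with a JSON
manifest.

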