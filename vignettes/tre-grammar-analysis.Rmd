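---
title: "Response-element grammar analysis of TR ChIP peaks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-element grammar analysis of TR ChIP peaks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trescan)
```

This vignette records the models, conventions and design decisions behind
the package: what each stage computes, which knobs matter, what the
synthetic generator does and does not emulate, and where genuinely open
choices were settled.

## Coordinate model and matching semantics

All coordinates are 0-based half-open; BED input is taken verbatim and
refFlat `txStart` is already 0-based, so no reader shifts coordinates
(a `one_based` flag converts 1-based peak-table dialects at the boundary).
Contig names are matched exactly and case-sensitively — there is no
"chr" aliasing.

The motif grammar covers single IUPAC words and dyads
`LEFT-spacer-RIGHT` where the spacer is a fixed length or an inclusive
range and spacer bases are unconstrained (the notation defines the spacer
only by length). Two deliberate choices:

* the pattern code `n` matches the unknown base N, but every other code
  — including two- and three-base degeneracies — does not. An unknown
  base should never satisfy a specific-base requirement, while `n`
  positions assert nothing.
* every overlapping occurrence is counted, with no greedy masking:
  occurrence statistics are raw rates, and masking would understate them.
  A footprint that is its own reverse complement is one biological site
  and is counted once; this is decided per pattern (is the composite
  self-reverse-complementary?), not per position, so a degenerate
  non-palindromic pattern that happens to match a symmetric sequence on
  both strands still counts twice — both orientations are real binding
  geometries there.

Dyad rows such as `nnnCCT-0-AGGnCA` and `nnnCCT-6-AGGnCA` are treated as
literal notations; the package imposes no everted/inverted taxonomy on
them, since orientation nomenclature cannot be settled from the notation
alone.

## Enrichment statistics

`region_occurrences()` scans each extracted region bidirectionally;
matches therefore never cross region boundaries, and a hit belongs to the
region containing it. The length-normalized rate is total hits over total
region bp. `fold_enrichment()` is a ratio of such rates. The default
background is the whole genome *including* the foreground: enrichment is
measured relative to overall genomic representation, and on real genomes
peaks are a negligible fraction. At desk scale (2 Mb, hundreds of peaks)
that approximation visibly compresses planted ratios, so
`exclude_foreground = TRUE` is available and is what the tests use to
verify the planted in-peak/background rate design. Both the
fraction-of-regions-with-hit and the per-bp rates appear in the report,
so either reading of an "enrichment" column can be checked; the fold
column itself is the rate ratio (matching length-normalized occurrence
semantics).

The co-localization z-score places length-matched windows uniformly on
the genome (`n_permutations` times, seeded), counts motif footprints
falling entirely inside them, and standardizes the observed in-peak
count. Windows more than half-covered by N are re-drawn so
assembly-gap-like regions cannot deflate the null. Counting uses one
genome-wide scan plus interval arithmetic rather than per-window
rescanning, which keeps 1000 permutations cheap.

## Consensus derivation and PWM scoring

De-novo discovery is out of scope; instead a deterministic seeded
alignment is used: for each top-ranked peak (ranked by score, ties broken
by coordinates for reproducibility) the single seed match closest to the
peak midpoint is chosen — ChIP signal is midpoint-centered, and
"best-scoring against the evolving matrix" would be circular — flanked,
re-oriented to the seed strand, and stacked into a PFM. Windows
containing N are skipped. The IUPAC consensus reads each column as a
single base at frequency ≥ `major_threshold` (0.6), otherwise as the
smallest IUPAC set covering ≥ `coverage_threshold` (0.8) of the column.

The PWM uses log2 odds against a background composition, by default the
scanned genome's observed base frequencies (uniform available as an
option), with a total pseudocount of 1 spread by the background (0.25
per base under uniform) to keep scores finite. `pwm_scan()` reports
windows at ≥ `score_fraction` (default 0.8) of the maximal attainable
score on both strands.

## Feature annotation

A single precedence-resolved map — promoter > 5′UTR > 3′UTR > exon >
intron > downstream > intergenic — is built once per annotation as
disjoint interval sets; peak midpoints are classified by lookup in that
map, and genome fractions are the same intervals' widths. Classifying by
midpoint (not any-overlap) makes the class distribution a partition that
sums to 100%. The promoter extent is 5 kb upstream of the TSS; the
downstream extent defaults to the same 5 kb (the natural mirror where no
separate figure is given) and both are configurable. Because classes are
resolved to disjoint intervals before any lookup, overlapping genes
cannot give a base two labels, and the per-peak and per-base views cannot
disagree — a property the tests assert against an independent per-base
oracle.

TSS profiles bin the signed, orientation-corrected distance (upstream
negative) from each peak midpoint to its nearest TSS over ±10 kb in
200 bp bins by default; both extents are configurable since frequency-plot
axes are a presentation choice.

Condition overlap calls a peak "shared" if it reciprocally overlaps a
peak of the other set — by ≥ 1 bp by default, with `min_overlap_frac`
to tighten. Any-overlap is the permissive reading of "unchanged between
conditions"; it is documented as an interpretation, and at high peak
density chance 1-bp touches inflate it, which is why calibration tests
use either spaced placements or a strict reciprocal fraction.

## Expression linkage

Raw intensities are transformed as `log2(x + 50)` and quantile-normalized
(cross-sample rank means; ties share their mean), the standard treatment
for bead-array intensities where the offset stabilizes low-intensity
probes. Regulated genes are called at linear |fold| ≥ 1.7 — i.e.
|log2 FC| ≥ log2(1.7) — and Benjamini–Hochberg adjusted p < 0.05.

The per-gene test is limma's moderated t by default. With three
replicates per group, an unmoderated Welch test has ~4 degrees of freedom
and its variance estimates are so noisy that even 1.5-log2 effects at
0.25 sd are recovered well under half the time; empirical-Bayes variance
shrinkage is the field's standard remedy for exactly this design and is
what bead-array pipelines apply. `method = "welch"` remains available
for comparison.

The "unaffected" class used in TSS-distance association is deliberately
strict — adjusted p ≥ 0.5 *and* linear |fold| < 1.1 — a clean null set
rather than "everything not significant", so that distance percentages
for unaffected genes are not contaminated by borderline responders. The
strong-regulation table uses a 2.5-fold floor.

The gap between a TSS and a peak is 0 when the TSS lies inside the peak,
otherwise the distance to the nearer peak boundary in half-open
coordinates; association fractions are per gene (a gene counts at
distance d if any peak is within d), which is the reading under which
"fraction of induced genes with nearby binding" is well defined.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes:
an i.i.d. genome (uniform composition by default), non-overlapping gene
models with exon/intron anatomy and UTR-trimmed CDS, two peak sets of
400 peaks each (200–500 bp) with 30% of each set planted as identical
intervals in both conditions, one DR4-type dyad planted at 2×10⁻⁵ per bp
outside peaks and ten times that inside, 40 induced and 20 repressed
genes among 300 (1.5 log2 effect, 0.25 sd noise, 3 replicates per group,
baseline log2 intensity ~ N(10, 1)), and half the induced genes given a
motif-bearing peak whose TSS distance is half-normal (sd 8 kb, truncated
at 25 kb) — so ~10% of them land within 1 kb. Problem sizes (2 × 1 Mb
contigs) are chosen so a full simulate-plus-analyze cycle takes seconds
on one CPU while leaving dozens of countable events per planted quantity.

A single master seed feeds a named sub-stream per stage (genome, genes,
peaks, plants, expression), so a stage can be regenerated independently
and identical configs give byte-identical bundles. Planted degenerate
positions are concretized uniformly over the code's A/C/G/T subset; no
plant overlaps another or straddles a boundary. Plants are placed after
peaks (background rate outside the peak union, in-peak rate inside), and
the guaranteed per-proximal-peak instances are written first so Poisson
plants cannot overwrite them; the ledger records every instance.

What the generator does *not* emulate, and what passing tests therefore
do not show about real data: genomic base composition structure (CpG
islands, repeats, mappability), read-level artifacts and peak-caller
behavior, promoter-biased peak placement (peaks are uniform except the
planted proximal ones, so feature folds are ~1 by design), correlated
probes, and bead-level noise. Conclusions about real ChIP data depend on
those properties; the tests establish correctness of the computations,
not biological generality.

Two generator options exist purely for constructions: `peak_tss_exclusion_bp`
keeps background peaks away from every TSS, and `gene_min_spacing_bp`
enforces a minimum inter-gene distance, which together make "exactly
half the induced genes have a ≤ 25 kb peak and nobody else does"
realizable; with 0 (the defaults) neither constraint applies.

## Numerical and degenerate-input choices

Empty region sets yield zero counts with NA (flagged) fractions rather
than errors; a zero background rate yields NA fold enrichment; a null
permutation distribution with zero variance yields NA z. Peak-ranking
ties break lexicographically. BH adjustment is `p.adjust`'s step-up,
cross-checked in the tests against a from-definition implementation.
Quantile normalization on a single sample is the identity after the log
transform. The consensus-seed alignment skips sequences whose flanked
window leaves the region.

## Known limitations

The scanner is exact-match only (no mismatch tolerance); probabilistic
matching is the PWM's job. The whole-genome background fold is biased
toward 1 when the foreground is a large genome fraction (see above).
The condition-overlap criterion is interval-based only; it does not model
peak-boundary jitter between conditions. Expression calls assume
approximately Gaussian log2 noise; heavy-tailed probe noise would
require robust alternatives.
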