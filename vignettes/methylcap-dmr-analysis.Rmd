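---
title: "Windowed DMR analysis of MBD-capture sequencing: model and methods"
author: "MethCapDMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed DMR analysis of MBD-capture sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

MBD-capture sequencing enriches the methylated fraction of a genome with
the methyl-CpG-binding domain of MBD2 and sequences the captured
fragments. The local density of aligned reads is then a proxy for
methylated-CpG density, and comparing two libraries window by window
locates differentially methylated regions (DMRs). MethCapDMR implements
that comparison as a fixed-resolution pipeline:

* The genome is tiled into non-overlapping 500 bp windows starting at
  base 1 of each chromosome; the terminal partial tile is kept for count
  conservation but never called (published DMR windows are all exactly
  500 bp, and report coordinates start at 1 mod 500).
* Each read contributes to exactly one window — the tile containing its
  leftmost aligned coordinate. Single-window attribution keeps counts
  integral, which the exact test below requires; it is also the one place
  this implementation can differ from fractional-overlap counters.
  Counting is strand-blind.
* Window counts are normalised to reads per million,
  `rpm = count * 1e6 / librarySize`, with the library size equal to the
  number of (uniquely mapped) reads supplied. An optional flag removes
  exact-coordinate duplicates first.
* A window is a DMR when, with strict inequalities,
  `max(rpm) > 20`, `max(rpm)/min(rpm) > 20` and `p < 0.001`.
  A zero minor library gives an infinite ratio, which passes the ratio
  filter — reported as `Inf` in the output tables. Adjacent passing
  windows are reported as separate rows (no merging).

## The window test

The upstream tool this filter originates from leaves the p-value model
unspecified; MethCapDMR defines it explicitly as a two-sided Fisher exact
test of the window's count against the remainder of each library:

```
            in window   rest of library
library A     a            libA - a
library B     b            libB - b
```

The two-sided p sums all hypergeometric point masses not exceeding the
observed one (with the conventional `1 + 1e-7` relative tie guard). This
choice is exact at any depth, symmetric in the two conditions, and
assumption-light; it is validated in the test suite against brute-force
table enumeration (to 1e-10 for all margins up to 50) and against the
classical implementation. No multiple-testing correction enters the
filter — the published cutoff is a raw p — but a Benjamini–Hochberg column
is emitted for information.

Because rpm ratios are quotients of small counts, the ratio filter
interacts with depth in a way worth stating plainly: a methylation
contrast of 0.9 vs 0.05 gives an asymptotic rpm ratio of 18, *below* the
ratio > 20 cutoff. At high coverage the observed ratio concentrates at 18
and such windows are never called; detection operates in the low-count
regime where the minor library samples zero or one read (infinite or
large finite ratios). This is a property of the filter itself, and it
motivates the simulator's default depth (below).

## Annotation

Each DMR receives exactly one feature category by any-overlap with
precedence `promoter > exon > intron > repeat > intergenic` (the order is
configurable; precedence is required because categories overlap, and the
default favours the regulatory interpretation). The promoter is the 5 kb
immediately upstream of the TSS on the gene's strand. Gene association
reports every gene whose TSS lies within ±5 kb of the DMR, labelled
`overlapStart` when the DMR contains the TSS and `upstream`/`downstream`
by the strand-aware side otherwise, with signed distances (negative =
upstream on the gene strand).

The CpG observed/expected ratio of the 500 bp window centred on each DMR
midpoint is

```
oe = n_CpG * L / (n_C * n_G)
```

with N bases excluded from the mononucleotide counts and breaking
dinucleotides; windows with no C or no G are flagged undefined and
excluded from distributions. For standard tiles the midpoint-centred
window is the DMR window itself. Per-category summaries report the median
o/e and the fraction above 0.6 — the conventional CpG-island threshold,
used descriptively and never as a filter.

## Gene-set statistics

Term enrichment and two-list overlap both use the upper-tail
hypergeometric probability `P(X >= k)`, computed from log-binomial
coefficients with log-sum-exp aggregation (exact at all sizes used; the
suite checks agreement with exhaustive summation to 1e-10 for populations
up to 200). Enrichment takes a user-supplied gene-to-term table and
background; significance is raw p < 0.01 with an informational BH column.
The overlap test's population defaults to 12,000, a promoter-array
universe. Gene identifiers are matched case-insensitively with set
semantics (a gene hit by several DMRs counts once). Identifier
harmonisation across platforms is deliberately the caller's problem.

# The simulator

`simulateGenome()`, `simulateMethylomes()` and `simulateCaptureReads()`
generate the study the analysis assumes, plus a ground-truth table, so
calibration and recovery are measurable.

**Genome.** Background sequence comes from a two-state dinucleotide
chain: bases are drawn from a fixed composition (GC 0.40) except
immediately after a C, where P(G) is pinned to `oe * P(G)`. This controls
the CpG observed/expected ratio (target 0.3) independently of GC content,
which an i.i.d. base model cannot do. CpG islands (1 kb, aligned to the
500 bp window grid, GC 0.60, target o/e 0.9) overwrite the background at
gene TSSs — promoter CGIs, the common genomic arrangement — with any
islands in excess of the gene count placed intergenically. Genes (4 kb,
two exons, alternating strand) and repeats (1 kb) occupy interleaved
non-overlapping slots; a sizing error names the per-slot footprint when
the requested features cannot fit. Realized o/e lands within about 0.05
of target (the chain slightly inflates the marginal G frequency after C),
comfortably separating the two classes.

**Methylomes.** Methylation is regional, not per-CpG: the analysis
operates at 500 bp resolution, so per-CpG states would add cost without
testable benefit. The genome is partitioned into regions — each CGI its
own region, the gaps tiled at 5 kb — and each region gets one level
shared by both conditions, drawn Beta(4, 6) (mean 0.4, a mid-methylated
soma-like background). Exactly `nDmrs` regions are planted as DMRs with
levels 0.9 vs 0.05, alternating direction. Default placement is in
CpG-poor background blocks away from genes, CGIs and repeats: in an
isogenic pair, promoter CGIs are constitutively unmethylated in both
lines, and differential blocks arise mostly elsewhere; placement is
configurable (`"cgi"`, `"repeat"`, `"any"`) for stratified checks.

The 5 kb DMR block length (10 windows) matches the published report
tables, where single loci span runs of consecutive 500 bp rows over
several kb. It also reflects the filter analysis above: with the ratio
cutoff exceeding the asymptotic effect ratio, each window is called with
probability ~0.4 even at the intended depth, so block-level recovery of
0.9+ requires blocks of roughly this span. Both readings were folded into
the default once; it is not adjusted per run.

**Reads.** A fragment of 400 bp (the captured size fraction) starting at
position p is sampled with probability proportional to

```
(number of CpGs in the fragment) x (methylation of the region at the
fragment midpoint) + epsilon
```

where epsilon is 1e-3 of the maximum raw weight, so fully unmethylated
DNA still receives a trickle of reads — the low-salt carryover seen in
real MBD capture. Each sampled fragment emits one 36 bp single-end read
from a uniformly chosen end (reads always lie inside their fragment). The
proportional-weight model is an assumption — no capture-efficiency noise
model is published for this protocol — and it is the one place the
simulator's realism is unverifiable; tests that pass under it show the
pipeline's statistics are calibrated and sensitive *given* this sampling
law, not that real capture behaves identically. Other omissions are
deliberate: no sequencing errors or quality strings, no PCR duplicates,
no paired ends, no mapping ambiguity, no copy-number variation.

**Depth.** Defaults use 22,000 reads per library over a 2 x 300 kb
genome (1,200 windows), sized so a planted DMR window sees about 30
captured reads on its hypermethylated side — the regime the filter
analysis above identifies as informative. Library sizes up to 1e6 are
supported; raising depth under the default contrast *reduces* ratio-filter
sensitivity, as explained above.

**Determinism.** One master seed drives everything through a fixed stream
order: genome (`seed`), methylomes (`seed + 1`), libraries A and B
(`seed + 2`, `seed + 3`). Identical configurations give byte-identical
FASTA/BED/TSV outputs; the pipeline's determinism is asserted at byte
level in the acceptance suite.

# Numerical and interface choices

* **Coordinates.** In memory everything is a 1-based inclusive `GRanges`.
  BED is 0-based half-open on disk, and the BED reader/writer is the only
  conversion point; all report tables print 1-based inclusive
  coordinates, matching published window tables whose starts are
  1 mod 500.
* **Ratio edge cases.** `max(rpm)/min(rpm)` is `Inf` when the minor count
  is zero (passes the filter, printed `Inf`) and undefined when both are
  zero (the window already fails the rpm filter; ratio reported NA).
* **Direction.** The side with the larger rpm; the ratio filter forbids
  ties among called windows, so calls partition into A-hyper/B-hyper.
* **Degenerate inputs.** Empty read sets give zero counts and flagged
  zero-valued coverage summaries; a CpG-free genome is a degenerate-weight
  error in the simulator; vacuous recovery (no planted DMRs / no calls)
  reports 1.0 with explicit flags rather than NaN.
* **Gene models.** A simple TSV (id, chrom, strand, TSS, span, exon
  lists) rather than GTF: the analysis needs only TSS, strand, span and
  exons. A GTF importer is a clean extension point.
* **Config.** YAML with unknown-key rejection at every level (typos fail
  fast), typed scalars, and the filter defaults 500/20/20/0.001, flank
  5000, enrichment p 0.01, population 12,000.

# Problem sizes

The test and acceptance suites run the simulator at 2 x 300 kb with
22,000–100,000 reads per library: 1,200 full windows, large enough for
the null-calibration bound (fraction of windows at p < 0.001 across 20
replicate read samplings) and the planted-recovery check (20 blocks,
sensitivity/precision at the default filter), while keeping a full suite
run in a couple of minutes on one CPU. These sizes are the package's
chosen calibration conditions, not limits of the method; the analysis
functions operate on whatever tiling the supplied genome induces.

# Known limitations

* The window test treats reads as independent draws; over-dispersion
  between biological replicates is out of scope (the design has no
  replicates), as are CpG-coupling normalisation, saturation analysis and
  local background models.
* Single-window attribution by leftmost coordinate means a read's window
  can differ from a fractional-overlap counter's choice by one tile.
* Feature percentages count each DMR once under the precedence rule;
  fractional multi-feature accounting is not implemented.
* The simulator's capture model is proportional and noise-free; see
  above for what that does and does not validate.
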