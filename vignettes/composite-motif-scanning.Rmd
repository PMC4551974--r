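---
title: "Quantifying OCT4-SOX2 composite elements in peak windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying OCT4-SOX2 composite elements in peak windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(composcan)
```

## The biological question

OCT4 and SOX2 maintain pluripotency by heterodimerizing on composite DNA
elements that juxtapose a SOX binding site (*CATTGTC*-like) and an OCT
binding site (*ATGCAAAT*-like). The spacing between the two half-sites
selects distinct protein-protein interfaces: canonical elements with
juxtaposed half-sites (as in the *Utf1* and *Hoxb1* enhancers) assemble a
different heterodimer configuration than elements with a three-nucleotide
spacer (as in the *Fgf4* enhancer). How much each configuration matters
for pluripotency correlates with how often its element occurs under
OCT4-SOX2 co-bound ChIP-seq peaks, and with how the expression of the
genes near those elements shifts when SOX2 point mutants disable one
configuration at a time.

`composcan` implements the genomics side of that argument as a tested
pipeline: count each composite class in summit-centered peak windows,
compare the positional distribution of the occurrences against matched
background sequence, link motif-bearing peaks to genes by distance to the
transcription start site (TSS), and classify per-gene expression fold
changes between mutant-rescued and wild-type-rescued cell lines.

## The motif model

The three composite classes are degenerate IUPAC *words*:

| class | word | structure |
|---|---|---|
| Hoxb1-like | `HWTTSWNATGYWDWD` | canonical, juxtaposed half-sites |
| Utf1-like | `HWTTSWNATGYWDGD` | canonical; differs from Hoxb1-like at one position (W vs G) |
| Fgf4-like | `HWTTSWNNNNATGYWDWD` | three-nucleotide spacer (four N positions) |

Matching is exact set membership per position — a word search, not a
position-weight-matrix score. There is no mismatch tolerance and no
threshold to tune; a window subsequence either is an expansion of the
word or it is not. Both strands are scanned by default (composite
elements are not strand-oriented relative to the peak summit); a
forward-only mode exists for sensitivity analysis. Overlapping
occurrences are all reported and deduplicated by (peak, motif, offset,
strand). Subject positions that are not A/C/G/T can never match any
motif position — a conservative treatment of ambiguous sequence rather
than an error.

Because the Hoxb1-like and Utf1-like words have an empty allowed-set
intersection at position 14 (`W` = {A,T} vs `G`), no concrete sequence
can belong to both classes. `patterns_disjoint()` proves this
analytically and the property is asserted in tests, so the two classes
never double-count a sequence.

The analytic chance-hit rate under an i.i.d. base model is the product
over positions of the summed allowed-base probabilities
(`expected_hit_rate()`). For the Hoxb1-like word under uniform bases this
is $6912/4^{15} \approx 6.44 \times 10^{-6}$ per offset per strand — the
null that calibrates the synthetic-data generator.

```{r motifs}
motifs <- default_motifs()
motifs[["Hoxb1-like"]]
expected_hit_rate(motifs[["Hoxb1-like"]])
```

## Windows, counts and background

Peaks are consumed as given (no peak calling): BED-convention 0-based
half-open intervals with an absolute summit position (when the summit
column is absent, the interval midpoint is used). Each peak contributes
the 100-bp window centered on its summit, `[summit - 50, summit + 50)`.
A window that would cross a chromosome boundary is *skipped with a
warning*, never truncated, so every window has identical length and the
positional distributions are comparable.

Per class the scanner reports two statistics: total occurrences and the
number of windows with at least one occurrence. For sparse composite
words the two rarely differ, but both are emitted because a reader of
the per-class counts cannot tell which convention was used to produce
them.

The positional distribution histograms each hit's center nucleotide
(`offset + floor(L/2) - width/2`) relative to the summit, in half-open
bins (default 5 nt, a smoothness/resolution compromise over 100 nt; the
bin width must divide the window width, and the last bin is closed).

Background windows are selected by seeded rejection sampling: uniform
over the genome, excluding any overlap with peak windows or previously
accepted background windows, requiring pure A/C/G/T sequence, and
requiring the window GC fraction to sit within a tolerance (default
±0.02) of the pooled peak-window GC. This plays the role that an
external tool's background selection plays in published figures of this
kind; the exact algorithm used there is not documented, so GC- and
length-matched sampling is our explicit, reproducible approximation.
Setting the tolerance to 1 reduces it to uniform non-overlapping
sampling.

## Linking peaks to genes and classifying expression

A gene is linked to every high-confidence motif-bearing peak whose
summit lies within 50 kb of its TSS. Distance is absolute and
boundary-inclusive; gene strand is ignored (no strand rule is defined
for this analysis). The mapping is deliberately one-to-many in both
directions — a peak may serve several genes and a gene aggregates
several peaks — as the least lossy choice. "High confidence" is a
pluggable predicate on the peak table (default: pass everything),
because the upstream peak set's own confidence criterion travels with
the peak file, not with this package.

Expression input is a normalized linear-scale matrix (genes × samples);
normalization itself is out of scope. Per condition, replicate samples
are averaged arithmetically on the linear scale. Both condition means
are then floored at 5 expression units — values below the floor are
treated as non-expressed background — and the fold-change class is

$$
\text{class} =
\begin{cases}
\text{up} & \text{if } \bar{x}_a/\bar{x}_b \ge 2 \\
\text{down} & \text{if } \bar{x}_a/\bar{x}_b \le 1/2 \\
\text{unchanged} & \text{otherwise,}
\end{cases}
$$

with log2 values computed from the floored means for heatmap-style
output. Flooring *before* the ratio is what makes the classification
stable for barely expressed genes, and it gives the classifier two easy
monotonicity properties that the tests assert: raising the floor can
only move genes toward "unchanged", and raising the threshold never
increases up + down. No significance test is attached — the
classification is purely fold-change based, by design of the analysis
this package reproduces.

```{r compare}
a <- c(Nanog = 120, Utf1 = 40, Klf4 = 3)
b <- c(Nanog = 30, Utf1 = 44, Klf4 = 4)
compare_conditions(a, b, floor = 5, threshold = 2)
```

## The synthetic-data generator

Every pipeline stage is testable without downloads because the package
generates its own inputs with known ground truth:

* **Genome**: i.i.d. bases at a configurable GC fraction (default 0.5,
  the background model of the analytic chance-hit rate).
* **Peaks**: non-overlapping 100-bp windows; each planted window
  receives one uniformly sampled concrete expansion of its class at a
  random offset and strand. In *strict* mode, each window is
  rejection-sampled until its only occurrence (any class, either
  strand) is the planted one, and the flanking sequence is then
  re-drawn wherever a chance occurrence or window-junction artifact
  appears, so genome-wide the occurrence set equals the planted set
  exactly. The default preset mirrors the full scale of the analysis:
  3,798 windows with 554/47/26 plantings, generated in seconds.
* **TSS table**: a configurable fraction of genes is placed within
  50 kb of a motif-bearing summit; the rest are placed in a motif-free
  genome tail beyond 50 kb of every motif-bearing summit (the tail,
  60 kb by default, exists precisely so that "unlinked" is achievable).
* **Expression**: baselines drawn log-uniformly in [20, 2000] (safely
  above the floor of 5); planted effects multiply one non-reference
  condition by a fold drawn log-uniformly from [2.5, 6] with up/down
  direction equiprobable; multiplicative log-normal noise (sd 0.1 on
  the natural-log scale by default) is applied independently per
  sample. Replicate counts default to 2/2/3, the wild-type/mutant
  design of the rescued ESC lines. Planted folds start at 2.5 rather
  than at the 2-fold threshold itself: an effect sitting exactly on the
  decision boundary is classified up or unchanged by a coin flip under
  any noise, so boundary folds cannot serve as recoverable ground
  truth.

What the generator does *not* emulate: real chromatin (repeats,
CpG islands, GC heterogeneity), ChIP-seq signal noise or peak-caller
artifacts, correlated gene expression, or the genomic sparsity of real
peak sets — the synthetic peak zone packs windows ~130 bp apart, so a
linked TSS is typically within 50 kb of many peaks, whereas real mouse
loci are far sparser. Passing recovery tests therefore demonstrates the
correctness of the bookkeeping (coordinates, strands, classes,
thresholds), not performance on real genomes.

## Numerical and design choices

* Coordinates are BED-style 0-based half-open throughout, including the
  0-based hit offsets — one convention everywhere beats two conventions
  with adapters.
* Matching semantics questions that the original description leaves
  open (strandedness, overlap handling) default to: both strands,
  all overlapping occurrences, deduplication by (peak, motif, offset,
  strand). Both knobs are exposed (`strands`, and the dual
  occurrences/windows-with-hit statistics).
* Degenerate inputs: a sequence shorter than the motif yields zero hits
  (not an error); an empty motif list yields an empty count table; an
  empty gene set yields an empty scatter table with zero counts;
  boundary-crossing windows are skipped loudly.
* All stochastic steps (background selection, every generator) take an
  explicit seed and restore the caller's RNG state, so a run manifest
  (parameters + seed + input checksums) is sufficient to reproduce
  every output byte for byte — asserted in the tests.
* Scales used by the test suite: the full 3,798-window preset for
  end-to-end recovery; a ~10-Mb uniform sequence (acceptance script) or
  ≥10^6 window offsets (tests) for chance-hit calibration; 200 genes /
  40 planted effects / 3 replicates for classification recovery. These
  sizes give the statistical checks 3-standard-error resolution while
  keeping any single check in the seconds-to-a-minute range.

## Limitations

* The per-class counts of a real analysis depend on the exact upstream
  peak coordinates and on the occurrence-vs-peak counting convention;
  with a different peak set the absolute counts will differ even though
  the class *ordering* (canonical ≫ spacer) is robust.
* Background matching is GC- and length-based only; it does not match
  repeat content or dinucleotide composition.
* The fold-change classifier is deliberately test-free; with few
  replicates it says nothing about significance, only about effect
  size.
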