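---
title: "Methods: tumor/normal aberration analysis on mapped read pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor/normal aberration analysis on mapped read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcnv)
```

## Scope and data model

`svcnv` analyzes **mapped read pairs** — it deliberately starts after
alignment and duplicate removal, which belong to an upstream mapping
pipeline. Every sample is a table of pairs (`sample_id`, `chrom1`, `pos1`,
`strand1`, `chrom2`, `pos2`, `strand2`, `insert`), 0-based half-open, with
the "innie" FR convention for concordant pairs: opposite strands, leftmost
read on the forward strand. The same convention is shared by the simulator
and the classifier, so the package is internally consistent without
modeling platform-specific strand chemistry.

Two library families matter in this problem domain: long-insert mate-pair
libraries (inserts ~2.3–2.6 kb, SD ~600–780 bp) that power structural-variant
detection and depth analysis, and short-insert paired-end libraries
(~90–145 bp) used for tile-count Z-score profiling of tumors and plasma
cell-free DNA (cfDNA).

## Depth-of-coverage copy-number analysis

Tumor and control fragment densities are compared in sliding windows.

**Why fragment starts, not read starts.** The two reads of a pair sit one
insert apart on the same fragment; as depth observations they are
perfectly correlated. Counting both would double the variance of window
counts while the ratio test below assumes Poisson counts, making p-values
anti-conservative (we observed spurious calls on neutral windows when
counting reads). Each pair therefore contributes one count at its leftmost
read start.

**The ratio test.** For a window with counts `x` (tumor) and `y`
(control) and sample totals `N_x`, `N_y`, the log2 ratio is
`log2((x/N_x)/(y/N_y))`. Its p-value treats `x/y` as a ratio of Poisson
variables via the Geary–Hinkley transform with a pooled per-window null
density `λ = (x+y)/(N_x+N_y)`:

$$t = \frac{\mu_y T - \mu_x}{\sqrt{\mu_y T^2 + \mu_x}},\qquad
  T = x/y,\ \mu_x = \lambda N_x,\ \mu_y = \lambda N_y,$$

two-sided against the standard normal. Windows with `y = 0` get an
undefined ratio and are excluded downstream rather than pseudocounted —
a pseudocount would manufacture arbitrarily extreme finite ratios.

**Window sizing.** The minimum window is the smallest `w` at which a true
density ratio of `2^{r'}` reaches two-sided significance `p'`, using null
expectations `μ = N·w/G` and alternative ratio `T = 2^{r'}N_x/N_y`; `|t|`
grows as `sqrt(w)`, so the boundary is found by integer bisection (tested
against an exhaustive 1-bp scan). Defaults `p' = 1e-4`, `r' = 0.6`; the
analysis window is 4× the minimum, the sliding step half a window — the
usual convention for this method family, configurable via `doc_config()`.
With read totals in the tens of millions on a gigabase genome these
defaults give windows in the tens of kilobases.

**Smoothing and significance.** Ratios are smoothed per chromosome by
Nadaraya–Watson regression with a Gaussian kernel over window midpoints;
the bandwidth is 2 window widths — wide enough to stabilize the track
without flattening focal events, and configurable. Significance is
controlled per chromosome by Benjamini–Hochberg at FDR `1e-4`
(`stats::p.adjust`); BH runs on the raw window p-values, and the
chromosome's symmetric reporting limit is the smallest `|smoothed ratio|`
among BH-significant windows, matching the order of operations the
published analysis describes (smoothing first, per-chromosome correction
second). Significant same-sign runs merge into regions.

**Accuracy caveat.** Because normalization is global, large aberrations
shift all neutral windows by `−log2(m)` where `m` is the relative total
mass change; and kernel smoothing ramps over ~1 bandwidth at segment
edges. Recovery accuracy is therefore assessed on the plateau — windows
interior to an implanted segment, clear of one bandwidth per edge — where
the mean smoothed ratio lands within 0.15 of `log2(CN_mix/2)`,
`CN_mix = purity·CN + (1−purity)·2`.

## PEM structural-variant detection

Insert statistics are estimated from intra-chromosomal FR pairs after
trimming the extreme 1% of inserts (0.5% per tail), so a small admixture
of discordant pairs cannot shift the mean. Signatures at `k = 4` SD:
different chromosomes → translocation; same strand → inversion; everted
order → tandem duplication; FR with insert above `mean + 4·sd` → deletion;
below `mean − 4·sd` → insertion. Note that for wide mate-pair libraries
`mean − 4·sd` is negative, so insertions are structurally undetectable at
this threshold — consistent with the near-absence of insertion calls in
cohorts sequenced with such libraries.

Same-signature pairs cluster by **exact single linkage**: two pairs join
when both their end positions lie within `mean + 4·sd` of each other.
This replaces a sliding-window graph construction with an
oracle-checkable equivalent (tests compare it to brute-force connected
components). Clusters keyed by (signature, strand pattern, chromosome
pair) become calls with two links — the min/max envelope of member read
ends per side — kept at minimum support 3 for tumors and 1 for controls,
so the germline filters see even weakly covered control variants. An
inversion legitimately yields two calls, FF at its left junction and RR
at its right, as signature-based callers do. Strand/order filtering then
removes internally inconsistent calls (mixed strand patterns, deletion
links that overlap).

## Germline subtraction: the window-filter cascade

Matched-control subtraction removes tumor calls overlapping a same-type
control call by ≥1 bp on both links. The window filter then removes a
tumor call when **both links lie within ±3 kbp of the links of a single
control variation** — link distance is the interval gap (0 when
overlapping, infinite across chromosomes), pairing tried in both orders,
type match not required. Reading "both links … of a control variation"
as *the same* control variation is the stricter and, we judge, intended
interpretation; matching either link against any control link
independently would remove calls on the coincidence of two unrelated
control clusters. Stage 1 runs against the matched control, stage 2
against the pooled panel; retention percentages are reported relative to
the input count, rounded half-up to one decimal. Removal decisions match
an exhaustive all-pairs distance oracle in tests, and on simulations with
germline variants shared across the panel, germline contamination among
retained calls drops to zero at stage 2 while all somatic truth calls
(≥10 kb from any germline variant) survive.

## Digital PCR

All partition assays — ~14,000-droplet reactions and 384-well plates at
0.5 haploid genome equivalents per well — share one Poisson path:
`λ = −ln(1 − k/n)` copies per partition with delta-method
`se = sqrt(p/((1−p)n))`; ratios propagate relative errors on the log
scale into 95% CIs. Deletion genotyping uses CI separation (deleted when
the tumor ratio's CI lies wholly below the matched normal's; not-deleted
when CIs overlap and the tumor point ratio is ≥90% of normal; otherwise
indeterminate) — the published analysis shows per-sample CIs without
stating a numeric rule, so the rule is explicit and configurable here.
Amplification calling uses a strict copy-difference threshold of 0.02
(with a 1e-9 float guard so a difference of exactly 0.02 is called
negative).
The cfDNA tumor-burden marker is the breakpoint/reference concentration
ratio in percent.

## cfDNA Z-scores and concordance

Tile counts (default 5 Mbp, non-overlapping) are normalized to 10 M reads
and standardized per tile against a control panel (mean and n−1 SD;
study-typical panel size 5, minimum 2 enforced). Non-overlapping tiles
are used even where "sliding" windows might be read: Z-scores need
independent bins for the panel SD to be meaningful. Concordance between
a tumor track and its cfDNA track is the Pearson correlation over tiles
overlapping (≥50% of the tile, configurable) DOC regions of one class,
with `F = r²(n−2)/(1−r²)` referred to `F(1, n−2)`; per-tile pairs are
correlated rather than per-region aggregates, matching the
many-points-per-class scatterplots such analyses present. Tile counts here use both read starts: the empirical panel SD
absorbs the within-pair correlation that the Poisson-based DOC test
cannot.

## The synthetic-data generator

`simulate_read_pairs()` emits mapped records directly — no sequence, no
alignment. Positions are sampled with density proportional to
`(purity·CN + (1−purity)·2)/2`; inserts are Normal, truncated at twice
the read length; fragments spanning an implanted junction (both reads
mapping cleanly on either side) are emitted with the corresponding
anomalous signature with probability zygosity × (purity if somatic).
Copy-number segments shape depth only and junction events shape pair
signatures only; an event needing both (a large deletion) is specified as
both a `cn_segment` and an `sv_event`. Insertions are novel sequence:
spanning fragments map closer together by the inserted length, which also
means only fragments longer than `size + 2·read_length` can witness them.

What the generator does **not** emulate — and hence what green tests do
not demonstrate about real data: GC and mappability bias, chimeric
artifacts, duplicate reads, mapping-quality structure, subclonal
heterogeneity, and reference errors. The defaults mirror the study
conditions this package re-enacts: mate-pair inserts ~2.5 kb (SD ~700),
droplet counts of 14,121 partitions, 192 wells per plate assay at 0.5
genome equivalents, a 5-sample control panel, and cfDNA fractions in the
0.01–0.25 range.

## Problem sizes and numerical choices

Tests and the acceptance script run on a 5 × 10 Mb genome with 50,000 to
200,000 pairs per sample (up to 10× insert coverage) — sizes chosen so
the full suite completes in minutes while every rate being verified
(recovery ≥95%, estimator bias <1%, CI coverage 94–96%) has enough
replicates to be stable across seeds. The SV-recovery suite uses a
tight-SD long-insert plan (mean 3,000, SD 150) so that all five event
classes, including insertions, are classifiable at the 4 SD threshold;
the DOC suites use the wide mate-pair plan (2,554/719). Monte-Carlo
calibrations use 500–10,000 replicates. Seeds flow from a single integer:
every simulation function takes an explicit seed, and identical
inputs + seed give byte-identical outputs.

Tie-breaks and degenerate inputs: clustering orders pairs canonically
before linkage so results are independent of input order; the first
matching control variation wins in the removal log (removal itself is
order-independent); saturated digital-PCR channels (`k = n`) are an
explicit error advising dilution; zero-variance Z-score tiles are `NA`;
single-window chromosomes smooth to themselves; exact Mann–Whitney p
(full enumeration with midranks) is used through combined n = 20, the
tie-corrected normal approximation beyond.

## Known limitations

* Global normalization couples all windows: near-tetraploid genomes or
  aberrations spanning much of the genome bias neutral windows away from
  log2 = 0; the package reports ratios relative to total mass, as the
  underlying method family does.
* Breakpoint resolution is limited to the link envelope (~1 insert);
  there is no split-read refinement.
* The per-chromosome BH limit is the minimum |smoothed ratio| over
  BH-significant windows; smoothing ramps at the edges of strong events
  can pull the limit low on that chromosome, admitting small-amplitude
  runs nearby. Region calls should be read together with their
  `n_windows` and mean ratio.
* Translocations are not sub-typed by strand orientation.
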