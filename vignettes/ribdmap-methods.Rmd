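---
title: "Mapping adaptive introgression with relative IBD scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping adaptive introgression with relative IBD scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribdmap)
```

## The problem and the statistic

When an admixed breed carries ancestry from two source breeds, genomic
regions that rose in frequency under selection after introgression stand out
as regions where the admixed population shares unusually much
identity-by-descent (IBD) with one source breed and unusually little with
the other. `ribdmap` scans for such regions with the relative IBD score.

The inputs are pairwise IBD segments between haplotypes, as produced
upstream by an HMM-based IBD detector (Beagle / Refined IBD); this package
deliberately does not infer IBD itself. For every genomic window \(W\)
(10 kbp by default, the practical lower bound for resolving a single gene)
two sharing fractions are computed:

\[
\mathrm{IBD}_{S1}(W), \quad \mathrm{IBD}_{S2}(W)
\]

the proportions of admixed genomes that are IBD with source breed 1 and
source breed 2 over \(W\), and the score is their difference:

\[
\mathrm{rIBD}(W) \;=\; \mathrm{IBD}_{S1}(W) - \mathrm{IBD}_{S2}(W)
\in [-1, 1].
\]

Positive scores indicate excess sharing with source breed 1, negative with
source breed 2. In the default *normalized* mode the two fractions are
rescaled to sum to one per window, so the score determines both fractions:
an rIBD of 0.5 corresponds to 0.75 / 0.25. A *raw* mode that reports the
unscaled fractions is kept for diagnostics, because windows supported by
little IBD evidence on either side renormalize aggressively.

## From segments to window calls

All interval arithmetic is done on a 0-based half-open representation;
the 1-based inclusive conventions of the segment and table file dialects
are converted exactly once, at the I/O boundary.

Per admixed unit and source side, the tracts of all supporting segments are
merged (a union, so overlapping tracts are counted once — delegated to
`IRanges`), and the unit is called IBD in a window when the merged tracts
cover at least `min_cov` of the window (default 0.5). Coverage is measured
against the actual window length, so the truncated terminal window of a
chromosome is scored like any other and merely flagged; summaries can
exclude flagged windows.

Three aggregation units are offered because "proportion of admixed
genomes" is ambiguous at the haplotype level:

* `haplotype` (default): each admixed haplotype is one genome — the finest
  unit consistent with haplotype-level IBD tracts;
* `individual`: an individual is IBD when either haplotype is;
* `pairwise`: every (admixed haplotype, source haplotype) pair is a unit,
  which weights sharing by how many source haplotypes support it.

"IBD with breed *k*" means IBD with at least one haplotype of any member of
breed *k*: sharing is treated as a property of the admixed genome, not an
average over source individuals. Windows with no evidence on either side
get rIBD 0 (not `NA`) so the genome-wide distribution is defined
everywhere; they remain identifiable through their zero counts.

The window grid tiles each chromosome with non-overlapping windows
(step = size). One score per 10 kbp interval is also what an overlapping
slide would report at these defaults, and the non-overlapping grid keeps
windows independent for the distribution summary.

Segments are filtered at read time by a LOD floor (default 3, the
conventional reporting floor of Refined IBD); source-source and
admixed-admixed pairs are skipped as irrelevant to the contrast, and every
skip is counted in a per-file report. A minimum-segment-length filter
exists but is off by default.

## Significance

Genome-wide, rIBD scores are approximately normal; the scan flags windows
beyond

\[
\bar{r} \pm k \cdot s, \qquad k = 3 \text{ by default},
\]

with \(\bar{r}\) and \(s\) the mean and sample standard deviation (n−1
denominator: the genome's windows are treated as a sample from the score
distribution) over all windows, pooled across chromosomes — one pair of
cut-offs per dataset, with per-chromosome summaries available as an option.
The two-tailed normal mass beyond 3 SD is 0.27%, conventionally quoted as
0.3%. Strict inequality is used at the cut-offs: a window exactly on a
cut-off is not called, which is conservative and affects ties with
probability zero under continuous scores. No further multiple-testing
correction is applied — the procedure *is* the empirical-normal cut-off
rule, not an FDR analysis.

Adjacent significant windows of one sign are merged into regions;
`max_gap_windows` (default 0) bridges short runs of sub-threshold windows
inside an extended signal.

As a worked consistency check, moments of 0.061 (mean) and 0.124 (SD) give
3-SD cut-offs of 0.433 and −0.311 by the formula above; a report computing
these from unrounded moments may print 0.432/−0.310, a difference confined
to rounding of unprinted digits.

## The synthetic-data generator

Real three-breed datasets with known introgression truth are rare, so the
package ships a generator whose ground truth is exact. Each admixed
haplotype is a mosaic of ancestry tracts with i.i.d. exponential lengths
(`mean_tract_bp`, default 100 kb — the scale expected a few tens of
generations after admixture); a tract derives from source breed 1 with
probability `p` taken at the tract midpoint (`baseline_p` = 0.5 by default,
overridden inside planted introgressed intervals by `p_local`). Each tract
emits `segments_per_tract` IBD segments spanning the tract to uniformly
chosen haplotypes of its source breed. Detection noise is modelled by
`drop_rate` (false negatives, default 0.05) and `spurious_rate`
(wrong-breed false positives per haplotype per Mb, default 0.1), with LOD
scores exponential with mean 10. The defaults represent a modestly noisy
but well-powered IBD call set; all draws follow a fixed documented order so
one seed pins the dataset byte for byte.

Under perfect detection the expected normalized rIBD of a window with true
source-1 ancestry fraction \(p\) is \(2p - 1\), which gives every recovery
test a closed-form target.

What the generator does *not* emulate: linkage-map heterogeneity,
coalescent tract-length correlations between haplotypes, genotyping error
structure, or the HMM's length-dependent detection bias. Passing recovery
tests therefore demonstrates that the windowing, aggregation and
significance machinery is correct, not that any particular real dataset
will behave this well.

### Edge effects and the recovery experiment

Because a tract's ancestry is assigned at its midpoint, the expected score
near a planted-interval boundary is attenuated over a scale of a few tract
lengths — a deliberate, known edge effect (tracts are not split at interval
boundaries). The package's parameter-recovery experiment (50 admixed
individuals, one 1 Mb chromosome, baseline \(p = 0.5\), a planted interval
at \(p = 0.9\) spanning the right half, tract mean 100 kb, 20 replicates)
therefore reads the plateau at least three tract lengths away from the
ancestry breakpoint on either side, where the residual attenuation
(\(\approx e^{-6}\)) is negligible against Monte-Carlo error. The recovered
means agree with \(2p-1\): 0.8 inside, 0 outside, within three Monte-Carlo
standard errors.

## Numerical choices

* Window calls compare merged coverage to `min_cov × window length` with a
  `1e-9` slack so fractional thresholds on odd-length windows are not lost
  to floating-point rounding; all quantities involved are otherwise integer
  base counts.
* Tables are written with 17 significant digits (`%.17g`), so
  write-then-read reproduces every double bit for bit, and the reader
  re-validates `rIBD = IBD_S1 − IBD_S2` to 1e−9 and the \([-1,1]\) range.
* Zero-evidence windows: score 0, flagged by zero counts, excludable in
  summaries (`exclude_zero_evidence`) for sparse datasets where the spike
  at 0 would shrink the SD and over-call the tails.
* Degenerate inputs: a chromosome shorter than one window yields a single
  truncated window; an empty segment set yields an all-zero score track
  (and a summary error below two windows, since an SD is undefined).

## Problem sizes in the test suite

The oracle-equivalence tests compare the pipeline against an independent
per-base brute-force recomputation on instances of up to 5 samples per
role and 50 windows — small enough to enumerate every base, large enough
to exercise overlapping tracts, both orientations of the segment pair
columns, all three aggregation units and both score modes. The recovery
experiment above uses 20 seeded replicates of the 1 Mb / 50-individual
design; the normal-tail calibration check draws 100,000 scores. These
sizes keep the full suite under a minute on one core while leaving every
claim tested at the scale stated here.

## Limitations

* The scan contrasts exactly two source breeds; with more candidates, run
  each pair separately.
* Cut-offs assume approximate normality of the genome-wide score
  distribution; strongly sparse or strongly structured datasets should be
  inspected with the histogram plot before trusting the tails.
* No gene-level annotation is performed; significant regions are exported
  as BED-compatible tables for downstream annotation tools.
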