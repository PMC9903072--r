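# ribdmap

Genome scans of **relative identity-by-descent (rIBD)** for mapping
adaptive introgression in an admixed breed with two source breeds.

When a breed arises from admixture, genomic regions favoured by selection
after introgression retain excess haplotype sharing with the source breed
they came from. Given pairwise IBD segments (from an upstream detector such
as Beagle / Refined IBD), `ribdmap` computes, per 10 kbp window *W*, the
fractions of admixed genomes that are IBD with each source breed and the
score

```
rIBD(W) = IBD_S1(W) − IBD_S2(W)   ∈ [−1, 1]
```

with the fractions normalized to sum to one per window (so rIBD = 0.5
means IBD_S1 = 0.75, IBD_S2 = 0.25). Windows beyond mean ± 3 SD of the
genome-wide score distribution (≈ 0.3% two-tailed under normality) are
flagged and merged into candidate introgressed regions. The package is
aimed at conservation-genetics and livestock researchers scanning admixed
breeds for introgression signals.

It ships:

* readers/writers for Refined-IBD-style segment files, population
  manifests, chromosome tables and windowed score tables (BED-compatible);
* the windowed scoring engine with haplotype / individual / pairwise
  aggregation units;
* significance summaries, cut-offs, significant-window lists and region
  merging;
* a synthetic IBD-segment generator with exact ground-truth local ancestry
  (expected rIBD has the closed form 2p − 1);
* genome-track and histogram plots;
* a CLI (`ribdmap simulate | compute | significant | plot`).

## Worked example

Simulate a 5 Mb two-chromosome genome for 30 admixed and 2 × 10 source
individuals, with one 200 kb interval (chromosome 1, 1.2–1.4 Mb) planted at
full source-1 ancestry, then scan it:

```r
library(ribdmap)

cfg <- simulate_config(
  n_admixed = 30, n_source1 = 10, n_source2 = 10,
  layout = genome_layout(c("1", "2"), c(3e6, 2e6)),
  introgressed_intervals = data.frame(chrom = "1", start = 1.2e6,
                                      end = 1.4e6, p_local = 1),
  seed = 42)
ds  <- simulate_ibd_dataset(cfg)
win <- compute_ribd(ds$segments, ds$layout, ds$manifest)
head(win[, c("chrom", "start", "end", "ibd_s1", "ibd_s2", "ribd")], 5)
#>   chrom start   end ibd_s1 ibd_s2  ribd
#> 1     1     0 10000  0.593  0.407 0.186
#> 2     1 10000 20000  0.559  0.441 0.119
#> 3     1 20000 30000  0.500  0.500 0.000
#> 4     1 30000 40000  0.534  0.466 0.069
#> 5     1 40000 50000  0.579  0.421 0.158

summ <- ribd_summary(win)
summ
#> rIBD distribution over 500 windows
#>   mean 0.0608, SD 0.2138
#>   cut-offs (mean +/- 3 SD): 0.7021 / -0.5805
#>   two-tailed normal mass beyond 3 SD: 0.270%

sig <- significant_windows(win, summ)
merge_regions(sig$positive, build_window_grid(ds$layout), max_gap_windows = 1)
#>   chrom   start     end     sign n_windows peak_ribd mean_ribd
#> 1     1 1240000 1400000 positive        16      0.86     0.791
```

The scan recovers the planted interval: 16 contiguous windows over
1.24–1.4 Mb exceed the upper cut-off (peak rIBD 0.86), while no window is
flagged on the negative side. The slight inward shift of the left boundary
is the expected edge attenuation of ancestry tracts (mean length 100 kb)
straddling the interval border; see the methods vignette
(`vignettes/ribdmap-methods.Rmd`).

The same analysis from the shell:

```sh
ribdmap simulate --out sim --seed 42 --n-admixed 30
ribdmap compute --ibd sim_ibd.tsv --manifest sim_manifest.tsv \
        --chromosomes sim_chromosomes.tsv --out run --min-lod 0
ribdmap significant --windows run_windows.tsv --out run
ribdmap plot --windows run_windows.tsv --out run
```

`compute` prints the first rows of the score table and a skip report;
`significant` writes the summary and the positive/negative region lists;
`plot` writes the genome track and the score histogram.

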