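# rohscape

Runs of homozygosity (ROH) and the distribution of functional variants
inside them, as a tested, reusable R pipeline.

When both copies of a genomic segment descend from one ancestral
haplotype (autozygosity), the segment shows up as a run of homozygosity.
Inbreeding therefore exposes recessive variation: at a site with
alternate-allele frequency *p*, the alternate homozygote occurs at
frequency *p* inside an ROH but only *p²* outside, so rare —
disproportionately deleterious — alleles are the most strongly enriched
as homozygotes inside ROH. `rohscape` is for population and livestock
geneticists who want to quantify that effect from sequence-level diploid
genotypes: it calls ROH from binned heterozygous-SNP counts, classifies
them by size (short < 100 kbp, medium 0.1–3 Mbp, long > 3 Mbp),
partitions annotated genotypes by functional class and ROH class, fits
the interaction regressions that compare enrichment between classes,
measures ROH sharing across individuals against a length-preserving
randomization null, and computes binned Weir–Cockerham F<sub>ST</sub> to
relate sharing to selection.

## The statistics at the core

For individual *i*, functional class *c* (deleterious, non-deleterious,
synonymous, nonsense, loss-of-function) and ROH class
*j* ∈ {S, M, L, R, N} (R = any ROH, N = outside), the partition tensor
counts sites by alternate-allele count *k* ∈ {0, 1, 2}:

- g<sub>i,R</sub><sup>c,k</sup> = g<sub>i,S</sub><sup>c,k</sup> + g<sub>i,M</sub><sup>c,k</sup> + g<sub>i,L</sub><sup>c,k</sup>,
  and g<sub>i,N</sub><sup>c,k</sup> = g<sub>i</sub><sup>c,k</sup> − g<sub>i,R</sub><sup>c,k</sup>
- f<sub>i,j</sub><sup>c</sup> = g<sub>i,j</sub><sup>c,2</sup> / g<sub>i</sub><sup>c,2</sup>:
  the fraction of *i*'s alternate homozygotes of class *c* lying in ROH class *j*

Enrichment differences between two classes are tested with the stacked
OLS model

&nbsp;&nbsp;&nbsp;&nbsp;f = β₀ + β₁·G + β₂·D + β₃·G·D + ε

where G is genome ROH coverage and D indicates the focal class; a
two-tailed t-test on β₂ tests an intercept difference and on β₃ a slope
difference between the per-class regressions.

ROH are called per individual from 10-kbp bins: the heterozygous-SNP
count of each bin is depth-corrected by `bin size / DP` (DP = covered
bases in the bin), a bin qualifies when its corrected count is at most
0.25× the individual's genome-wide mean, and maximal runs of qualifying
bins ≥ 10 kbp become segments.

## Worked example

```r
library(rohscape)
library(dplyr)

cohort <- simulate_cohort(demo_layout(),
                          sim_params(n_pops = 1, n_per_pop = 20, seed = 1))
bins   <- bin_heterozygosity(cohort)
roh    <- classify_roh(call_roh(bins))
prof   <- coverage_profile(roh, cohort$layout, cohort$samples$sample)

f  <- roh_proportions(partition_genotypes(cohort, roh))
fr <- f |>
  filter(roh_class == "R",
         func_class %in% c("deleterious", "non_deleterious")) |>
  left_join(prof[, c("sample", "g_r")], by = "sample") |>
  mutate(d = as.integer(func_class == "deleterious"))
fit <- fit_interaction_model(fr, f, g_r, d)
fit
#> Interaction regression f ~ G * D  (n = 40 )
#>   term estimate std.error statistic   p.value
#>  beta0 0.008775  0.005060     1.734 9.143e-02
#>  beta1 1.761263  0.054600    32.257 3.670e-28
#>  beta2 0.007797  0.007156     1.090 2.831e-01
#>  beta3 0.295444  0.077217     3.826 4.991e-04
```

β₃ > 0 with p < 0.05: the proportion of deleterious homozygotes falling
inside ROH rises faster with inbreeding than the non-deleterious
proportion — rarer alleles are preferentially exposed. The fitted lines
can be turned into expected count changes; with the inside/outside
slopes 1568.76 and −98.67 (counts per unit of coverage):

```r
predict_counts(slope_in = 1568.76, intercept_in = -57.63,
               slope_out = -98.67, intercept_out = 693.63, delta_g = 0.10)
#> # A tibble: 1 × 4
#>   change_in change_out   net baseline
#>       <dbl>      <dbl> <dbl>    <dbl>
#> 1       157        -10   147      694
```

A 10-point increase in ROH coverage is expected to add 157 deleterious
homozygotes inside ROH, remove 10 outside, a net gain of 147; a
non-inbred genome (G ≈ 0) carries about 694.

Other entry points: `nucleotide_diversity()` (π and π-out),
`sharing_track()` / `sharing_null()` (per-bin sharing with the
randomization null), `fst_bins()` / `aggregate_track()` /
`correlate_tracks()` (binned θ and its correlation with sharing),
`run_pipeline()` (everything from one YAML/list config),
`plot_roh_coverage()`, `plot_enrichment()`, `autoplot()` on fits.

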