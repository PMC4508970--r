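---
title: "Methods: ROH detection, functional-variant partition, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, functional-variant partition, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscape)
```

`rohscape` analyses how predicted-function variants distribute across
runs of homozygosity (ROH) in diploid genomes. This vignette is the
package's own account of the methods: the models, the tunable
parameters and why their defaults are what they are, what the synthetic
cohort emulates (and does not), and the numerical conventions a user
should know before trusting — or extending — the results.

## The ROH caller

Heterozygous genotypes are counted in fixed-width bins (default 10 kbp,
`bin_size`) per individual. Because parts of a bin may be poorly
covered by sequencing, the raw count is corrected by `bin size / DP`,
where DP is the number of covered bases in the bin: a half-covered bin
with 4 observed heterozygotes is treated as 8. Two conventions follow
from the correction being a ratio estimator:

- **Usability window.** A bin whose relative coverage (DP / bin width)
  falls outside 0.5×–2× of the individual's mean relative coverage is
  flagged unusable: the correction would amplify noise more than
  signal. Unusable bins carry no corrected count and *interrupt* runs —
  the caller never declares homozygosity across a no-data region. A
  `bridge` parameter (default 0 bins) can relax this for datasets with
  scattered dropout.
- **Threshold.** A bin qualifies as homozygous when its corrected count
  is ≤ `threshold_factor` (default 0.25) × the individual's genome-wide
  mean corrected count per usable bin. The mean SNP density, not the
  sequencing depth, is the reference: depth is already absorbed by the
  correction factor, and the quantity being thresholded is a SNP count.
  Both the factor and the reference are parameters, so the alternative
  reading (thresholding raw counts) can be reproduced by supplying
  pre-corrected tracks.

Maximal runs of consecutive qualifying bins form segments; segments
shorter than `min_length` (default 10 kbp — one bin, the minimum size
considered) are dropped. Boundaries are bin-grid aligned; no sub-bin
refinement is attempted because the method is defined on bins. On
genomes of ≤ 100 bins the caller is tested for exact equality against a
brute-force re-implementation, and on simulated cohorts with
error-free genotypes it recovers ≥ 95% of planted tracts spanning at
least two bins with at most one bin of boundary slack — a tract's edges
generally fall mid-bin, so one bin is the resolution limit.

Nucleotide diversity π is the corrected heterozygote count per kbp over
usable bins; π-out restricts to usable bins not overlapping any ROH of
that individual, and is never below π when ROH exist, since ROH bins
are low-heterozygosity by construction.

## Size classes and coverage

Segments are classified short (S), medium (M) or long (L) with
boundaries `short_max` = 100 kbp and `long_min` = 3 Mbp: S is
`length < short_max`, M is `short_max ≤ length ≤ long_min`, L is
`length > long_min`. Ties at exactly 100 kbp go to M and at exactly
3 Mbp to M, matching the class definitions "smaller than 100 kbp" and
"larger than 3 Mbp". The alternate conventions (50 kbp / 2 Mbp and
150 kbp / 4 Mbp) are reached by changing the two thresholds. Coverage
proportions G_S, G_M, G_L, G_R are segment-length sums over total
genome length; because segments are disjoint and each carries exactly
one class, G_S + G_M + G_L = G_R holds to machine precision and is
asserted, not assumed.

## The partition tensor and proportions

For each individual, every annotated site with a non-missing genotype
contributes to exactly one ROH class (the class of the unique segment
containing its position under the half-open convention, else N) and to
the R and total marginals. Reference homozygotes (k = 0) are tallied
but never enter the proportions: only alternate alleles carry
functional annotations, so f is defined on alternate homozygotes
(k = 2) only. When an individual has no alternate homozygote of a
class, f is reported missing rather than zero — a 0/0 division is a
lack of evidence, not evidence of absence. The N (outside-ROH) class is
defined by subtraction, g_N = g_total − g_R, which is the only reading
consistent with the additivity of the S/M/L classes.

## Regression and prediction conventions

Class contrasts use the stacked model `f = β0 + β1 G + β2 D + β3 G D`,
fitted by ordinary least squares with two-tailed t-tests on β2
(intercept difference) and β3 (slope difference). The comparison
variable is always the 0/1 indicator D; pairwise size-class contrasts
(L vs M, L vs S, M vs S) set D = 1 for the larger class and use each
class's own coverage as G. No multiple-testing correction is applied
across the three pairings by default.

`predict_counts()` converts fitted lines of homozygote *counts* against
coverage into expected changes for a coverage increase ΔG. Components
are rounded half-away-from-zero; the net change is computed from the
unrounded components and then rounded, so slopes 1568.76 and −98.67
with ΔG = 0.10 give +157, −10 and a net of +147 (156.876 − 9.867 =
147.009), and the outside-ROH intercept 693.63 rounds to a baseline of
694 at G ≈ 0. The alternative (summing the rounded components) is
available via `net_from = "rounded"`.

Group splits at the low/high inbreeding cutoff (default G_R = 0.20) put
the tie at exactly 0.20 into "high" — the boundary individual is at
least as inbred as the cutoff. Breed contrasts use Welch's
unequal-variance two-tailed t-test; with only "two-tailed t-tests"
specified, the unequal-variance form is the safer default for groups
of different sizes and spreads. Pearson correlations and their exact
t-based two-tailed tests are computed from the textbook sums (and are
cross-checked against `stats::cor.test` in the test suite).

## Sharing, the randomization null, and F~ST~

Sharing counts, per 10-kbp bin, the number of *individuals* with at
least one overlapping ROH (half-open intersection); `count = "pairs"`
reports `choose(k, 2)` instead, since the statistic could equally be
defined on pairs. The demographic null preserves each individual's
segment count and length multiset exactly and re-places segments
uniformly — chromosome drawn proportional to length among chromosomes
that fit, position uniform, resampled on within-individual overlap,
with no re-alignment to the bin grid. Observed sharing maxima are
compared with the null distribution over replicates.

Per-site Weir–Cockerham variance components (a, b, c) use the
genotypic, observed-heterozygosity-aware two-level formulation;
per-population sample sizes shrink site-by-site with missing
genotypes. Within bins the estimator is the **ratio of sums**
Σa / Σ(a+b+c) — not the mean of per-site ratios; the two differ and the
multi-locus ratio-of-sums is the standard combination. Bins with no
polymorphic site are missing, not zero; small negative θ values are an
estimator property and are kept. 10-kbp tracks are averaged
missing-aware into 500-kbp windows before correlating F~ST~ with
sharing. Haplotype-based selection statistics (iHS/rSB) are out of
scope, but `correlate_tracks()` accepts any externally produced
500-kbp track in the same layout.

## The synthetic cohort

The simulator exists so that every downstream stage is testable without
external data, with truth files for recall. Its generative law is the
package's modelling statement:

- **Genotypes.** Outside planted IBD tracts, Hardy–Weinberg:
  (1−p)², 2p(1−p), p². Inside a tract, homozygous with P(alt hom) = p.
  A `het_error_rate` (default 0.001) flips truly homozygous calls to
  heterozygous, emulating genotyping error.
- **Sites and frequencies.** Site positions are uniform per chromosome
  at per-class densities. Each site draws an ancestral frequency from a
  Beta law with class-specific mean (deleterious 0.05, non-deleterious
  0.20, synonymous 0.30, nonsense/LoF 0.03; concentration 2, i.e.
  strongly right-skewed for rare classes), then per-population
  frequencies follow a Balding–Nichols hierarchy with expected
  differentiation `pop_divergence` (default F = 0.05, the order
  observed between related livestock breeds). These means are stated
  modelling choices, not estimates for any real species.
- **Tracts.** A per-class plan (counts Poisson per individual, lengths
  uniform within class bounds) with a per-individual intensity
  multiplier U(0.3, 1.2); larger tracts are placed first, uniformly,
  resampling on overlap. An optional `sweep` plants a shared tract
  (and, optionally, allele-frequency divergence) at a fixed locus as a
  positive control for the sharing null and the F~ST~ correlation. An
  optional `tract_freq_mult` raises or lowers deleterious frequencies
  inside tracts of chosen size classes, to plant class-specific
  enrichment.
- **Depth.** Covered bases per bin are the bin width times a capped
  log-normal fraction (`depth_sdlog`, default 0.15), feeding the
  caller's correction and usability window; per-site DP written to VCF
  scales the mean depth by the bin's covered fraction.

The default conditions — the 50-Mbp, four-chromosome `demo_layout()`
with the default tract plan — were fixed once, on two grounds. First,
scale: total site counts give per-individual homozygote totals of the
same order as a sequenced cattle cohort (roughly 10⁵ annotated sites
and ~10³ deleterious alternate homozygotes per genome), so the noise
level of the f statistics is realistic even though the genome is 50×
shorter. Second, regime: with these frequency laws the proportion of a
class's homozygotes falling in ROH saturates in every class once
coverage exceeds roughly 0.3 — above that point the deleterious and
non-deleterious curves rise in parallel and the slope contrast β3 is
not identifiable. The default tract intensity therefore keeps cohort
coverage in the ~3–30% band (cohort means near the lower end of the
range reported for real dairy breeds), where the contrast the package
is built to measure actually expresses. Test problem sizes (20
individuals for the enrichment checks, 10–12 for recall and sharing,
200 null replicates, 500 regression replicates, 10⁵ Monte-Carlo draws)
are the package's chosen desk-scale defaults throughout.

What the simulator deliberately does **not** model: recombination and
coalescent history (tract placement is uniform, not genealogical),
linkage disequilibrium beyond the planted tracts, phasing, multi-allelic
sites and indels, annotation error, and reference bias. Passing tests
therefore demonstrate that the *methods* are implemented correctly and
behave as the theory predicts under the stated law — not that real
genomes satisfy that law. In particular, real ROH length distributions
encode inbreeding age, which the uniform length plan ignores.

## Numerical conventions and degenerate inputs

- Coordinates are 0-based half-open internally; VCF emission converts
  to 1-based. A site at exactly a segment's end position is outside it.
- All-unusable tracks yield an empty ROH set with a warning; empty ROH
  sets give π-out = π, zero coverage, and put all partition mass in N.
- Constant-coverage designs are rejected as rank-deficient rather than
  silently dropped terms; fewer than 5 observations per indicator group
  is an error.
- Zero-variance inputs give missing correlations; two identical
  constant groups give t = 0, p = 1.
- Randomized placement retries up to 1000 times per segment and then
  aborts naming the individual — the packing, not the data, is at
  fault.
- All simulation and null-replicate functions take explicit integer
  seeds; identical seeds give byte-identical outputs.

## Known limitations

The caller's resolution is one bin: ROH shorter than ~2 bins are
unreliably detected, and at SNP-array densities short-ROH recall
collapses (demonstrated by `downsample_to_array()`). The 0.25×
threshold references the individual's own genome-wide mean, so highly
inbred genomes (mean corrected count already depressed) have a
conservative threshold. The interaction model treats per-individual f
values as homoscedastic, though their binomial noise shrinks with
homozygote counts; with the default site numbers this is negligible at
desk scale. The sharing null conditions on segment lengths but not on
local SNP density, so genomes with strongly heterogeneous callability
would need a callability-aware null.
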