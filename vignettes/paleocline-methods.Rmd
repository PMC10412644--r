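---
title: "Methods and models in paleocline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in paleocline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocline)
```

`paleocline` analyzes ancient-DNA datasets in which each individual is
represented by pseudohaploid calls — one randomly drawn allele per
ascertained SNP — the standard representation for genomes below a few
fold coverage, where diploid genotypes cannot be called reliably. This
vignette explains the models behind each analysis stage, the tunable
parameters and their defaults, what the synthetic generators do and do not
emulate, and the numerical choices a user may want to know before trusting
or changing a default.

## Data model

Genotypes are integer allele-2 counts (derived-allele counts once
polarized) in an individuals × sites matrix, with ploidy 1 for
pseudohaploid and 2 for diploid individuals and `NA` as the missing
sentinel. Pseudohaploid individuals are represented natively rather than
as forced-homozygous diploids, so allele totals in frequency estimates are
correct (a ploidy-1 call contributes one observed allele, not two).
`write_eigenstrat(haploid_as_diploid = TRUE)` exports homozygote-coded
diploids for interoperability. Coordinates are 1-based (EIGENSTRAT
convention); only the unpacked text dialect of the format is supported.

Panel filters mirror the construction rules of ascertained ancient-DNA
panels: a minor-allele-frequency floor in a reference group (default
threshold 0.1, the usual Yoruba-ascertainment rule), removal of transition
(C/T, G/A) sites for transversion-only panels, and a per-individual
treatment rule in which non-UDG library individuals have transition calls
masked while UDG-treated individuals keep them. In dataset merging, allele
codes are reconciled by swap, and by strand complement only at
transversion sites; strand-ambiguous A/T and C/G sites that do not match
directly cannot be reconciled safely and are dropped with their own
counter, as are sites whose allele union exceeds two (triallelic).

## f-statistics and the weighted block jackknife

The estimators are the plain frequency products,
`f4(A,B;C,D) = mean (p_A − p_B)(p_C − p_D)`,
`f3(O;A,B) = mean (p_O − p_A)(p_O − p_B)`,
`f2(A,B) = mean (p_A − p_B)^2`, each over the sites at which *its own*
populations are all observed (no global site intersection — the behavior
of the "use all SNPs" mode of the standard tools). No small-sample or
inbreeding correction is applied anywhere: the package's comparative uses
are on pseudohaploid data, where within-individual heterozygosity is
unobservable, and an uncorrected estimator applied uniformly cancels in
comparisons. This is a deliberate, documented divergence from the
corrected modes of AdmixTools; absolute f3/f2 values are not comparable
between the two.

Standard errors come from a weighted delete-one-block jackknife over
contiguous blocks of at most 0.05 Morgans (5 Mb physical fallback when a
chromosome lacks genetic positions); a new chromosome always starts a new
block. For unequal blocks the Busing-style weighting is used; with equal
blocks it reduces exactly to the classic delete-one formula, which is a
unit test. Blocks of 0.05 M are far longer than typical linkage
disequilibrium, which is what makes the jackknife variance honest; the
calibration test checks 95% CI coverage of a true-zero f4 across 200
replicates.

The f4-ratio `alpha = f4(A,O;X,C) / f4(A,O;B,C)` estimates B-related
ancestry in X when A is a sister of B and C represents the other source.
Its SE comes from leave-one-block-out recomputation of the *full ratio*
rather than the delta method: near a small denominator the delta method
understates the variance, while the ratio jackknife remains stable. A
`weak_denominator` flag is raised when the denominator's |Z| falls below 3
(configurable).

`admixture_weights()` is a deliberately simplified qpAdm: with rights
R_0..R_m (R_0 the fixed base) it solves
`f4(R_0,R_i;X,O) = sum_j w_j f4(R_0,R_i;S_j,O)` for weights summing to 1
by least squares weighted with the block-jackknife covariance of the
residual f4 vector, then reports the residual quadratic form against a
chi-square with `m − k + 1` degrees of freedom and per-weight SEs from
leave-one-block-out re-solves. It does not implement qpAdm's rank-rotation
machinery and is not numerically identical to it; its guarantee is
parameter recovery on simulated admixture graphs, which the acceptance
tests verify, not replication of any published chi-square value.

The continuity scan computes `f3(Outgroup; X, anchor)` per test individual
— the anchor being the highest-coverage local Mesolithic-era individual —
and flags an individual as discontinuous when its upper 95% CI bound falls
below the lower bound of the *oldest* individual's statistic. Individuals
with fewer than 500 overlapping sites (10,000 for f4-based scans) are
excluded and listed rather than plotted into noise.

## Conditional nucleotide diversity

CND is the mismatch rate of two pseudohaploid genomes over their shared
ascertained sites; under the assumption that the two haploid draws come
from unrelated members of one population it estimates conditional
heterozygosity, a within-population-diversity proxy whose expectation is
`2·mean(p(1−p))` over the panel frequencies — the closed form the tests
check. Pairing is oldest-first by calibrated age, consecutive pairs,
skipping known kin by swapping in the next individual; with an odd roster
the oldest leftover is dropped and reported. Pairs are the unit the method
defines; the pooled group estimate (site-count-weighted, jackknifed over
summed block contributions) is an extension and labeled as such. Diversity
is maximal near equal ancestry proportions in a two-source mixture — the
property test behind the "admixture raises CND" check.

## The anchor continuity test

Conditioning on sites heterozygous in a high-quality *diploid* anchor
fixes the anchor's own derived proportion at exactly 0.5. Forwards in
time, drift is a martingale, so descendants of the anchor's population
keep the same expected proportion; backwards in time the proportion drops,
because derived alleles observed at intermediate frequency tend to be
young. That asymmetry only exists under a skewed site-frequency spectrum:
with the uniform ascertainment-mimicking root frequencies the generator
uses for f-statistics, derived/ancestral symmetry forces every conditional
proportion to 0.5 and the method has no signal. The generator therefore
offers `root_dist = "sfs"` (density proportional to 1/p), which the anchor
tests use. Because the package conditions on an ascertained panel rather
than all-site genotypes, absolute proportions are biased by ascertainment;
all tests compare proportions *between* individuals and never to an
absolute external value. A pseudohaploid anchor is rejected outright —
heterozygosity is unobservable in a single drawn allele.

## Kinship

The pairwise statistic is P0: the mismatch proportion in non-overlapping
1 Mb physical windows (the convention of the READ method; windows with no
overlap are dropped). The cohort-median normalization assumes most pairs
are unrelated and no population structure; a bimodality diagnostic on the
mean-P0 distribution warns when that assumption looks violated, and an
explicit external normalizer (e.g. `2·mean(p(1−p))` from a reference
panel) is supported for small cohorts. Expected normalized P0 is `1 − phi`
(phi the kinship coefficient): 1 unrelated, 0.875 second degree, 0.75
first degree, 0.5 identical. Class cutoffs sit at the midpoints (0.9375,
0.8125, 0.625) and live in one configurable constant; a value exactly on a
cutoff resolves conservatively to the less-related class. A pair is
reported *confident* when the SE-scaled distance to the nearest adjacent
cutoff exceeds 1.96. The screen reruns each cohort after excluding
individuals below 0.1× mean depth, recomputing the normalizer, mirroring
standard confirmation practice.

Trio genealogy enumeration assigns each pair a catalog relationship
(parent-offspring or full sibs for first degree; half sibs,
grandparent-grandchild, avuncular or double first cousins for second;
unrelated otherwise) with every orientation and maternal/paternal line
choice, then *constructs* each candidate as an explicit pedigree with
latent parents and grandparents through a union-find. A candidate survives
only if the construction is consistent (single mother and father per
individual, sexes match roles, acyclic) and the realized kinship
coefficients — computed recursively on the constructed pedigree — match
the observed degrees exactly; this rejects label combinations that are not
jointly realizable. Shared maternal lines require identical mt
haplogroups; shared paternal lines among males require compatible Y
haplogroups, where a truncated label is compatible with any refinement of
itself (prefix rule), reflecting that low-coverage individuals often
cannot be placed below a major clade. An ancestor whose calibrated
interval lies entirely later than its descendant's is excluded. With
`assume_uniparental = TRUE` the stronger working assumption applies: a
related pair sharing an identical uniparental haplogroup must be connected
through the corresponding uniparental line, which collapses the model sets
to the matrilineal/patrilineal families such data are usually read as.

## Cost surfaces and least-cost paths

Percent water cover maps to friction classes 1–16 exactly as
`{0→1, (0,20]→2, (20,40]→4, (40,60]→6, (60,80]→8, (81,100]→16}` — open
land travels easiest, large water bodies act as near-barriers without
being impassable — and ice-sheet cells get +999 *after* reclassification.
Path distance runs a multi-source Dijkstra over the 8-connected grid with
edge cost `d(u,v) · (cost_u + cost_v)/2 · VF(u→v)`: center-to-center
distance (octile metric), average of the two cell costs (the convention of
the GIS path-distance tools), and an inverse-linear vertical factor
`VF = 1 + theta/45` with the vertical relative moving angle theta in
degrees (positive uphill), impassable beyond |theta| > 5°, floored at
0.05. Gentle descents are therefore cheaper than flat moves, which makes
distances direction-dependent — a property the tests check explicitly.
The slope constant (1/45 per degree) and floor are configurable because
GIS implementations differ in their exact inverse-linear parameterization.
For grids in geographic degrees, east-west distances are scaled by
cos(latitude); the fixtures use projected units so the oracles stay exact.
Accumulated costs are abstract travel-cost units; no conversion to
kilometers is attempted, and the regression consumes them directly.
Backlink rasters use the eight-direction code (1 = E clockwise to 8 = NE)
pointing to the predecessor; path extraction follows backlinks from any
destination to its nearest source. Fixture truth for the optimality tests
comes from an exhaustive depth-first enumeration over simple paths — a
different algorithm than the Dijkstra it validates.

## The admixture isolation-by-distance regression

Observations are per-individual allele-sharing responses (an f4 of the
form f4(Outgroup, X; FarSource, NearSource), or an estimated admixture
proportion) joined with least-cost distances from the two source regions.
Two exclusion rules are applied and annotated, never silently: SNP-capture
individuals (batch effects on f4) and responses based on fewer than 5,000
sites. The model is ordinary least squares `y ~ a·x + b·z + c` with
two-sided t-tests and no multiple-testing correction (a single
pre-specified model). "Possible leverage points" are made reproducible as
Cook's distance > 4/n (configurable), with original and refit models
reported side by side. The distance variant (minimum, median or total over
a source point set) is a configuration axis; minimum is the default
headline choice. The time-trend regression of ancestry proportion on
calibrated age uses years BP as the predictor, so a *negative* coefficient
means the proportion rises toward the present.

A geometry caveat discovered while building the synthetic validation: if
the sampled sites lie on a line between the two source regions, the two
distances are affinely dependent and the two-predictor model is
unidentifiable — any partial coefficient is noise even when the combined
cline signal is overwhelming. The synthetic cline therefore scatters demes
over a latitudinal band as wide as the cline is long, with the source
points flanking the region off the scatter, which is also the geometry of
the real continental datasets this design imitates. Users fitting the
two-distance model on their own data should check the correlation of their
distance columns before interpreting partial coefficients.

## Synthetic data: what it does and does not emulate

Allele frequencies evolve along a user-specified admixture graph under
Balding–Nichols drift: a child at drift F from parent frequency p draws
from `Beta(p(1−F)/F, (1−p)(1−F)/F)`, giving mean p and variance
`F·p(1−p)` — closed-form moments that make exact oracles possible (e.g.
`E[f2] = 2F·E[p(1−p)]` between two leaves at drift F from a common
parent). Admixture nodes mix parental frequencies deterministically. Root
frequencies are Uniform(0.05, 0.95) to mimic a common-SNP ascertained
panel, or 1/p-skewed (`root_dist = "sfs"`) where an unascertained spectrum
matters. Individuals are Binomial(ploidy, p) draws with i.i.d. missingness
and symmetric per-allele flip error. Pedigrees transmit one random
parental allele per site (Mendelian), with pseudohaploid sampling applied
last.

Defaults encode the study conditions the validation targets: cline demes
with ancestry linear from 1 to 0 across the line, source-divergence drift
F = 0.02, post-admixture deme drift 0.005, 5% missingness, 0.2% call
error; 50,000 sites in 100 jackknife blocks (a 5-Morgan synthetic
chromosome at 0.05 M blocks) for calibration and recovery experiments;
20,000 overlapping SNPs for the kinship power tests; a population
turnover simulated at branch drift F = 0.1 per lineage (a
forager/farmer-scale replacement); an anchor scenario whose pre-anchor
individual sits F = 0.2 of drift above the anchor (an Upper-Paleolithic-
scale separation) with descendants at F = 0.02 steps below it.

What the generators deliberately do not emulate: sequence-level reality
(reads, mapping, postmortem damage beyond a symmetric error rate,
contamination), linkage (sites are exchangeable, so the block jackknife is
exercised under independence, not under real LD), real ascertainment
chains, recombination-aware haplotypes, and spatially continuous
populations. Passing tests therefore demonstrate estimator and pipeline
correctness under the stated models, not robustness to damage,
contamination or LD misspecification in real data.

## Problem sizes, runtime and determinism

The validation experiments use 50k sites and 100 blocks (calibration,
recovery, continuity), 20k sites for kinship power, grids of at most 22 ×
22 cells for routing, and 20-deme clines for the regression — sizes at
which every experiment is exact or has power near 1 while the whole suite
runs in minutes on one CPU. All generators take explicit seeds and restore
the caller's RNG state; `run_pipeline()` re-runs byte-identically under
the same config and seed, and its manifest records the package version,
seed, thresholds and every excluded individual with its reason.

## Known limitations

Uncorrected f-statistics (see above); a simplified qpAdm whose chi-square
is not calibrated against the original implementation; Anchor conditioning
on ascertained panels rather than all-site calls; kinship limited to
first/second degree with a fixed relationship catalog (no third-degree
relationships, no likelihood-based methods); routing on modern-style
rasters with no paleo-coastline modeling; pure-R Dijkstra that is
comfortable at fixture scale but not meant for continental 30-arc-second
grids.
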