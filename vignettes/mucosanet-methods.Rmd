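---
title: "Methods: paired mucosal 16S analysis with mucosanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired mucosal 16S analysis with mucosanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucosanet)
```

## Scope

`mucosanet` implements the downstream statistical analysis of paired
vaginal/endometrial 16S abundance data: matrix conditioning, alpha and
beta diversity, permutation tests of cohort separation, supervised
biomarker discovery (PLS-DA VIP and LEfSe-style effect sizes), and
Pearson co-occurrence networks with Louvain communities and keystone
ranking.  Upstream read processing (quality filtering, chimera removal,
OTU picking, taxonomic assignment) is out of scope: the package starts
from a species-by-sample count table, a taxonomy map and per-sample
habitat/outcome labels.

Because the analyses are meant to be testable without sequencing data,
the package ships a first-class synthetic cohort generator whose output
has the statistical structure the pipeline assumes.  Everything below
describes both the analysis methods and what the generator does and does
not emulate.

## Matrix conditioning

* **Low-count filter** (`min_count_filter`): species with a total count
  of at most `min_reads` (default 5) across all samples are removed.
  The threshold is read as "totals of five or fewer are noise"; an
  override is available because the convention (<= 5 vs < 5) differs
  between pipelines.
* **Relative abundance** (`to_relative`): rows are closed to sum to 1.
  No rarefaction or scaling normalization is applied - diversity is
  computed on counts, everything multivariate on conditioned relative
  abundances.
* **Prevalence filter** (`prevalence_filter`): keeps species present in
  at least 20% of samples (inclusive boundary), independently of
  abundance.  Prevalence is always computed on the raw values of the
  cohort being analysed, so each comparison (and each per-habitat
  network) applies the filter to its own samples.
* **Good's coverage** (`goods_coverage`): `1 - singletons / reads` per
  sample, the usual check that libraries were sequenced deeply enough.
* **Normal scores + standardization** (`rank_normalize_standardize`):
  each species column is mapped through van der Waerden scores
  `qnorm(r/(n+1))` of its mid-ranks and then centered/scaled to mean 0,
  variance 1.  The rank step makes each column Gaussian-shaped
  regardless of the raw distribution; the choice of van der Waerden
  scores over an empirical-quantile interpolator is deliberate: it is
  tie-safe (heavily tied zero counts get a common mid-rank score) and
  has no boundary infinities.  Zeros participate in the ranking, so the
  transform preserves prevalence semantics.  Constant columns carry no
  information and are dropped with a warning.

## Diversity and ordination

Alpha diversity is observed species and the Shannon index (base 2 by
default, so a uniform 4-species community scores 2 bits), both computed
on counts.  Beta diversity is Bray-Curtis dissimilarity
(`vegan::vegdist`), which on closed rows equals half the L1 distance.
PCoA eigendecomposes the double-centered Gower matrix; axes with
negative eigenvalues are reported in the eigenvalue vector but excluded
from coordinates and from the variance denominator, and no
Lingoes/Cailliez correction is applied - reporting raw negative
eigenvalues is more transparent than silently repairing them.
Hierarchical clustering uses complete linkage (`stats::hclust`), whose
merge heights are monotone.

## Permutation and exact tests

`anosim_test` and `permanova_test` are implemented from their
definitions (rank-based R statistic; pseudo-F from squared
dissimilarities) and tested against vegan and against exhaustive
enumeration at small n.  Labels, not distances, are permuted; p-values
use the `(b + 1) / (n_perm + 1)` convention, which can never return 0 -
with 999 permutations the smallest reportable p is 0.001.  Other floor
conventions exist in the field; this one is documented and fixed.

`mann_whitney_u` enumerates the exact conditional distribution over
mid-ranks whenever `n1 + n2 <= 12` (this handles ties and returns
exactly 1 for identical multisets) and otherwise uses the tie- and
continuity-corrected normal approximation.  `freeman_halton` is the
exact r x c independence test: recursive margin-constrained enumeration
of all tables, summing the probabilities of those no more probable than
the observed table (with a 1e-7 relative guard against float ties).
All-zero rows/columns are dropped first; budgets (N <= 200, r*c <= 12)
keep enumeration tractable.

`bh_two_stage` is the adaptive two-stage linear step-up: stage 1 at
`q/(1+q)` estimates the null count `m0 = m - r1`; stage 2 steps up at
`q*m/m0`, reducing to plain BH at `q` when stage 1 rejects nothing.
This variant always rejects at least as much as one-stage BH at the
same `q`.  The returned adjusted values satisfy
`rejected == (adjusted <= q)`.

## Biomarker discovery

PLS-DA is NIPALS partial least squares against a centered 0/1 class
indicator.  With a univariate response the inner loop converges in a
single pass per component; components successively deflate X.  VIP
scores use the standard definition weighted by the response variance
explained per component and satisfy `sum(VIP^2) = p` exactly - an
identity asserted in the tests on every fit.

The reported VIP is the **leave-one-out mean**: the model is refit once
per left-out sample and the per-species mean and SD of the n VIP
vectors are reported.  The n folds are the complete set of leave-one-out
resamples; their order is irrelevant to the mean.  The default of 2
latent components is exposed as a parameter.

Fold ratios compare cohort-mean relative abundances (high over low, so
FR >= 1); a zero low mean falls back to a pseudocount of half the
smallest non-zero relative abundance, flagged in the output.

`lefse_like` gates species through (1) a two-sided Mann-Whitney test at
alpha = 0.05, (2) two-stage BH FDR at q = 0.10 applied **across all
tested species**, and (3) a minimum of 5 non-zero observations.  The
FDR adjustment deliberately spans all species of the comparison rather
than only the already-significant subset: adjusting a pre-selected set
of small p-values provides no error control at all (essentially every
gated species would survive), and the whole-comparison adjustment is
what makes the null-calibration property of the suite hold.  Survivors
are scaled to counts-per-million and scored as `log10` of the absolute
mean of the raw class-mean difference and the first-axis LDA-projected
difference (`MASS::lda`), floored at 0; no additional LDA-score cutoff
is applied beyond the gates.

One operating characteristic worth knowing: with a single true
biomarker, an FDR gate calibrated at q = 0.10 still admits at least one
false companion with probability close to q.  A "the planted species is
the only discovery" event therefore saturates near 90% even for very
strong effects; the recovery tests assert 100% recovery of the planted
species and an 80% floor on exclusivity.

## Co-occurrence networks

Networks are built on prevalence-filtered, rank-normalized data:
pairwise Pearson correlations with two-sided t-distribution p-values
(n - 2 df); an edge exists when p <= 0.05.  Edges carry the sign of r
and a thickness category 1-8 from p-value decades ((1e-2, 5e-2] is 1,
(1e-3, 1e-2] is 2, ..., <= 1e-8 is 8) - a reproducible, monotone
realization of "eight significance categories".  Louvain community
detection runs on |r| edge weights (classic Louvain requires
non-negative weights; signs remain available as edge attributes) at
resolution 1, with 10 randomized node-order restarts; the best
partition's modularity is recomputed from scratch and that recomputed
value is what is reported.  Degree and betweenness (unweighted Brandes,
unnormalized) come from igraph; keystone species are the top-betweenness
nodes with degree and species ID as tie-breaks.  A permutation test of
community co-membership for a species set of interest is provided as an
explicitly labelled stand-in (the statistic: largest number of set
members sharing one community, against random equal-size node sets).

## The synthetic cohort generator

`generate_cohort` draws, per sample, a latent Gaussian vector with
block-structured correlation (within-block constant rho >= 0, which is
always positive semi-definite); log abundance is a profile baseline
plus planted biomarker shifts plus the scaled latent noise; structural
zeros are applied per sample x species; rows are closed to compositions;
and counts are multinomial at a log-normal depth (CV 0.3 around
`depth_mean`, default 18000 reads).  Two habitat profiles exist: a
*Lactobacillus*-dominant one (species 1 holds 92% of the expected mass
by default, the mid-range of the 90-95% share typical of vaginal
communities) and a polymicrobial one whose expected shares follow a
1/rank power law.  `generate_study` concatenates one cohort of each
profile into the study-shaped two-habitat dataset.

Three design choices deserve explanation because the defaults encode
them:

* **Dispersion structure.** Minor taxa receive 1.5-2x the baseline
  log-noise (growing with rarity rank), while the dominant species of
  the lactobacillus profile receives 0.5x.  A dominant fraction that
  stays inside a narrow 90-95% band *implies* small dispersion, and
  minor taxa in real communities are strongly overdispersed.  Without
  this asymmetry, compositional closure makes every minor taxon shift
  more (in log units) between habitats than the dominant species does,
  and the dominant species would not be the most discriminant feature -
  contradicting what the profiles are meant to emulate.
* **Dropout gradient.** Structural-zero probability rises linearly from
  0.25 (most abundant rank) to 0.9 (rarest) by default.  This creates
  the prevalence gradient that makes a 20% prevalence filter
  meaningful, and it mirrors the sporadic detection of rare taxa in
  real 16S data.  The dominant species of the lactobacillus profile is
  exempt: it is structurally present.
* **Closure-aware targets.** Profile targets describe the *realized*
  (post-dropout) expected composition; pre-dropout weights are inflated
  by the survival probability so that the dominant share centres on
  `dominance_fraction` rather than drifting above it.

What the generator does **not** emulate: phylogenetic signal, read-level
error and chimeras, taxon-specific depth biases, longitudinal dynamics,
and real taxon co-exclusion (negative latent correlation).  Passing the
recovery tests therefore demonstrates that the pipeline's machinery
recovers planted structure of the assumed form, not that it is robust
to every failure mode of real amplicon data.

A consequence of compositional closure worth noting for benchmark
design: when correlated blocks make up a large fraction of the
community, the shared row-sum term induces *negative* cross-block
correlations that are genuine features of the closed data (and, through
|r| weights, can bridge communities).  The block-recovery benchmark
therefore embeds its three rho = 0.8 blocks in a 60-species even
community (`power_exponent = 0`) where closure coupling is negligible;
the study-shaped presets keep the 1/rank profile.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data
at deliberate desk scale: cohorts of 10-34 samples x 15-60 species,
199-999 permutations, 10-200 seed replicates per calibration and 50-100
per recovery experiment - sizes chosen so every property is measured on
hundreds of independent draws while a full run stays in the tens of
seconds.  Every stochastic step (generation, permutation tests, Louvain
restarts, the pipeline itself) takes an explicit seed, restores the
caller's RNG state, and records its conditions in the run manifest;
rerunning with an identical manifest reproduces every output
byte-for-byte.

## Known limitations

* Tests are run per comparison; no cross-comparison multiplicity
  control is attempted.
* The exact Freeman-Halton test refuses tables beyond its enumeration
  budget rather than falling back to Monte-Carlo (the flag is reserved).
* Pearson co-occurrence on rank-normalized abundances is not a
  compositionality-aware estimator (no SparCC/SPIEC-EASI); closure can
  induce edges, which is why networks are built on prevalence-filtered,
  rank-normalized data and signs are retained for inspection.
* With groups as small as 4 samples, permutation tests and PLS-DA run
  but are annotated low-power; interpret them accordingly.
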