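---
title: "Models and methods behind microtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtraj)
```

## The analysis problem

`microtraj` analyses longitudinal 16S amplicon sequence variant (ASV) data
from hosts sampled repeatedly across an ordered sequence of travel phases
— `BeforeTrip`, `OnTheWay`, `Staying`, `OnTheWayBack`, `AfterTrip` — as in
skin-swab time series collected every 2–3 days around a polar expedition.
The questions it operationalises are: how far does a host's community
drift from its pre-trip baseline, how quickly and completely does it
return, and which environmental and lifestyle covariates track the
magnitude of change.

Because raw expedition data require sequencing archives and denoising
outside this package's scope, every stage is exercised against a
synthetic-data generator whose ground truth is known exactly. The
generator is first-class, tested code, not a fixture.

## Synthetic study model

`generateStudy()` draws, per host and sampling day:

* **Counts.** A Dirichlet-multinomial: per-sample proportions
  $p \sim \mathrm{Dirichlet}(\theta\, m_{\text{phase}})$, counts
  $\sim \mathrm{Multinomial}(N, p)$ with $N \sim \mathrm{Poisson}$ around
  the design's mean depth (default 20,000 reads). The concentration
  $\theta$ (default 200) sets sample-to-sample compositional wobble;
  $\theta = \infty$ collapses to a plain multinomial at the phase mean. A
  Dirichlet-multinomial was chosen because real ASV tables are
  overdispersed relative to a multinomial, and because its marginal mean
  equals the phase composition, giving clean ground truth.
* **Phase composition.** The default design anchors each phase's mean
  composition to phase-averaged phylum-level profiles observed on two
  expedition hosts (`antarcticPhylumProfiles()`), spread over ASVs within
  each phylum by a fixed geometric weight series so a few ASVs dominate
  each phylum, as on real skin. Host B has no usable return-leg profile,
  so its `OnTheWayBack` row is reconstructed as the renormalized midpoint
  of `Staying` and `AfterTrip`. Because composition is piecewise constant
  within a phase, within-phase recovery dynamics are *not* emulated;
  tests of recovery-rate ordering therefore use explicitly constructed
  trajectories.
* **Batches.** Samples are assigned to three sequencing batches in
  contiguous blocks of processing order, and per-feature log10 offsets
  (s.d. 0.2, batch 1 as reference) multiply the counts — the confounding
  that batch correction must remove. Offsets are part of the design and
  derive deterministically from the seed.
* **Lifestyle and weather.** Per-phase Bernoulli probabilities for
  sunblock, cosmetics and outdoor activity (outdoor activity peaking
  during the Antarctic stay), and phase-specific normal draws for
  temperature, relative humidity, pressure, wind speed and direction on
  outdoor days. Indoor days carry *no* weather record, so the indoor
  imputation rule is always exercised; a fraction (default 15%) of
  outdoor entries is additionally blanked to emulate logging gaps.
  Calendar time is an integer day offset from the study start; there are
  no time zones or fractional days.

What passing tests on this generator do **not** show: robustness to
compositional zeros structured by phylogeny, to depth confounded with
phase, to non-normal weather dynamics, or to gradual within-phase
community drift. The generator emulates the design, not the ecology.

## Environmental covariate preparation

Weather variables are prepared in three fixed steps:

1. **Indoor constants.** Any sample with `outdoor = FALSE` has all five
   variables *set* to standard indoor reference conditions — 20 °C, 40 %
   relative humidity, 1013 hPa, 0 m/s, 0° — overriding recorded values.
   The override (rather than fill-only-missing) reading was chosen
   because an indoor swab does not experience the outdoor weather of that
   day at all; overrides are reported so the choice is auditable.
2. **Interpolation.** Remaining gaps are filled linearly in calendar
   days, per host and per variable; leading/trailing gaps take the
   nearest observation. Interpolation is per host because interpolating
   across hosts on different continents is physically meaningless. Wind
   direction is interpolated on the raw degree value; circular
   interpolation is deliberately out of scope and this is a known
   limitation near the 0°/360° wrap.
3. **Standard scaling.** Each variable is transformed to mean 0, s.d. 1
   using the population (divide-by-$n$) convention of the common
   machine-learning scaler; the sample convention is available via
   `population = FALSE`. Zero-variance columns scale to zeros with a flag
   rather than an error, and the stored centre/spread makes
   `unscaleEnvironment()` an exact inverse.

## Abundance preparation

* **Filtering.** A feature is kept iff its occurrence (fraction of
  samples with a non-zero count) is strictly greater than 0.1 **and** its
  total count is strictly greater than 5. Both thresholds are strict and
  configurable; the boundary cases (occurrence exactly 0.1, total exactly
  5) are dropped.
* **Pseudocount and log transform.** Zeros are replaced by half the
  global minimum non-zero value of the table, then everything is
  log10-transformed. The pseudocount is recorded so the transform is
  invertible where counts were positive.
* **Batch correction.** `combatAdjust()` implements the parametric
  empirical-Bayes location/scale model: feature-wise standardization
  given the covariate design, per-batch location ($\gamma$) and scale
  ($\delta^2$) estimates shrunk toward normal / inverse-gamma pooled
  priors by iterated conditional posterior means (relative tolerance
  1e-4, cap 500 iterations), then back-transformation restoring covariate
  effects. Host and trip phase are protected covariates by default, after
  an iterative multicollinearity prune that drops the later column of any
  pair with $|r| \ge 0.9$. The test suite cross-checks the implementation
  against an independent ComBat implementation to ~1e-6. One numerical
  caveat is intrinsic to the model: because EB shrinkage deliberately
  leaves a sliver of the batch signal, a second adjustment pass is a
  strong contraction but not an exact fixed point; the tests assert the
  contraction, not exact idempotence. Constant features pass through
  unadjusted with a flag.
* **Back-transform and relative abundance.** Corrected values are
  exponentiated back to the count scale and normalized per sample to the
  simplex. Taxonomic aggregation keys on the *full* lineage prefix at the
  requested rank (so homonymous names in different lineages stay apart)
  and pools unmapped features into `Unclassified`; it conserves
  per-sample totals exactly. Temporal smoothing uses a centered 5-point
  moving average whose window shrinks symmetrically at the series edges.

## Diversity and hypothesis tests

Alpha diversity is computed on filtered *counts* (not corrected
abundances): observed features; bias-corrected Chao1
$S + F_1(F_1-1)/(2(F_2+1))$, defined even when no doubletons exist;
Shannon entropy in base 2 (bits; the base is configurable and recorded);
and Simpson's $1-\sum p_i^2$. Phase comparisons use Kruskal–Wallis with
tie correction followed by pairwise two-sided Mann–Whitney U tests with
Bonferroni multiplication capped at 1.

Beta diversity is Bray–Curtis,
$d(x,y)=\sum_i |x_i-y_i| / \sum_i (x_i+y_i)$, computed on the
batch-corrected relative abundances, mirroring the pipeline order
(correction precedes community comparison). Ordination is classical
metric PCoA — Gower double-centering of $-D^2/2$, eigendecomposition,
coordinates from positive eigenvalues only, variance explained relative
to the positive-eigenvalue sum, negative eigenvalues reported but unused;
axes are defined up to sign, so all comparisons are made through
distances. Group structure is tested with one-way PERMANOVA (pseudo-F on
the total/within partition of squared dissimilarities) with a
label-permutation null and the $(1+b)/(1+m)$ p-value convention, which
can never return zero; permutations are unrestricted across the samples
given to the test, which the pipeline runs per host.

## Baseline trajectories and the resilience index

For a host, every sample's **dissimilarity from baseline** is its mean
Bray–Curtis distance to all of that host's `BeforeTrip` samples (a
baseline sample's self-distance is excluded from its own mean). The
per-phase **resilience index** is

$$
RI \;=\; \left[\frac{2\,(D_0-D_L)}{(D_0-D_L)+(D_0-D_N)} - 1\right]
\times \frac{1}{T_N - T_L},
$$

with $D_L, D_N$ the trajectory values at the phase's first and last
sample and $T_L, T_N$ the corresponding day offsets. The reference
dissimilarity $D_0$ is a genuine convention choice, so it is an explicit
required mode:

* `"zero"` (default): $D_0 = 0$ collapses the bracket to
  $(D_L-D_N)/(D_L+D_N)$, making the index positive exactly when the
  community moved toward baseline during the phase — the interpretation
  the index is meant to carry ("higher = quicker or more complete
  return") holds by construction;
* `"baseline_self"`: the mean within-baseline pairwise distance, so the
  index measures return relative to the baseline's own wobble;
* `"global_max"`: the host's maximum trajectory dissimilarity.

The chosen mode is recorded in outputs, and published index values are
not used as correctness targets anywhere precisely because the reference
convention is not standardised. Phase endpoints use the first/last
sampled values rather than phase means (endpoints define the recovery
question; means would dilute direction), durations are whole days, and
phases with fewer than two samples or a vanishing bracket denominator are
flagged, never silently dropped. Under the default mode the index scales
as $1/\text{days}$ and its bracket flips sign when $D_L$ and $D_N$ swap.

## Association statistics

The per-sample "community shift" response has two modes, both logged,
because the underlying regression response is ambiguous in longitudinal
designs: `successive` (default) — Bray–Curtis distance between each
sample and the host's previous sample — or `from_baseline`, the
trajectory above. Continuous factors are tested against the shift by
per-factor ordinary least squares (slope, $R^2$, two-sided slope p);
binary lifestyle flags by the point-biserial correlation (identically
Pearson on the 0/1 coding, $t$ p-value on $n-2$ d.f.). Taxon-level
screens use Spearman's rank correlation for continuous factors
(Pearson on mid-ranks; two-sided $t$ approximation, matching the common
scientific-Python convention rather than R's exact small-sample default)
and point-biserial for binary ones, with Benjamini–Hochberg adjustment
across the whole taxon-by-factor matrix — the matrix-wide scope is the
conservative choice in the absence of a stated convention. The per-taxon
phase screen is a deliberately transparent Kruskal–Wallis + BH ranking,
labelled as a screen: it stands in for multivariable mixed-model
association tools without claiming to reproduce them.

## Numerical and degenerate-input policy

Distance matrices are validated (symmetry to 1e-12, zero diagonal) at
every entry point. All-zero samples, empty groups, single batches, or a
host without baseline samples are hard errors naming the offender;
constant inputs to correlations and zero-variance regression factors are
flagged results, not errors, because they occur routinely in screened
data. Permutation p-values include the observed statistic in the null
set. PCoA drops numerically negative eigenvalues below a relative 1e-10
threshold.

## Problem sizes used by the checks

The packaged checks run the full two-host default design (about 88
samples by 120 ASVs), 200 null PERMANOVA simulations at 20 samples with
999 permutations each, a 60-sample batch-correction recovery study, and
exhaustive label enumeration on 6 samples as the PERMANOVA oracle. These
sizes were chosen to make every statistical property measurable with
stable margins while keeping a full run in the low tens of seconds.

## Reproducibility

A single seed drives everything: the design derives its batch offsets
from it, `generateStudy()` seeds its draws with it, and the pipeline
fans it out to per-stage sub-seeds by fixed offsets so any stage can be
re-run in isolation. Two runs with the same config are bit-identical,
and the run manifest records the seed, parameters, pseudocount, dropped
features and covariates, and per-stage dimensions.

```{r example}
res <- runPipeline(defaultRunConfig(seed = 7))
res$resilience$A
```
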