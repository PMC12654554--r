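# microtraj

Longitudinal skin-microbiome trajectory analysis for travel designs with
ordered phases — the kind of study where hosts swab their skin every 2–3
days before, during and after an expedition to an extreme environment,
and the questions are: *how far did the community drift from its
pre-trip baseline, how fast did it come back, and what environmental and
lifestyle factors track the change?*

The package is aimed at microbiome analysts working with 16S ASV count
tables plus sample metadata (host, day, trip phase, sunblock/cosmetics/
outdoor logs, sequencing batch) and gappy weather series. It covers the
full post-denoising pipeline:

* **Synthetic study generation** — a Dirichlet-multinomial generator
  emulating a two-host Antarctic expedition (five ordered phases:
  `BeforeTrip`, `OnTheWay`, `Staying`, `OnTheWayBack`, `AfterTrip`) with
  known ground-truth composition, injected batch effects, lifestyle
  logs and missing weather entries, so every downstream stage is
  testable without any sequencing download.
* **Environmental preparation** — indoor days are set to reference
  indoor climate constants (20 °C, 40 %, 1013 hPa, 0 m/s, 0°), remaining
  gaps are interpolated linearly in calendar days per host, and each
  variable is standard-scaled to mean 0, s.d. 1.
* **Abundance preparation** — feature filtering (occurrence > 0.1 and
  total count > 5, both strict), half-minimum pseudocount and log10
  transform, parametric empirical-Bayes batch correction with protected
  covariates (location/scale model with shrinkage toward pooled priors),
  back-transform, relative abundance, lineage-keyed taxonomic
  aggregation and moving-average smoothing.
* **Diversity** — observed features, bias-corrected Chao1, Shannon
  (bits), Simpson; Bray–Curtis distances, PCoA, one-way PERMANOVA with a
  permutation null, and Kruskal–Wallis phase comparisons with Bonferroni
  post hocs.
* **Resilience** — per-sample dissimilarity-from-baseline trajectories
  and a per-phase resilience index

  ```
  RI = [ 2(D0 − DL) / ((D0 − DL) + (D0 − DN)) − 1 ] × 1/(TN − TL)
  ```

  where `DL`/`DN` are the trajectory values at the phase's first/last
  sample, `TL`/`TN` the corresponding days, and `D0` an explicit
  reference convention (`zero`, `baseline_self` or `global_max`). Under
  the default `D0 = 0`, `RI > 0` means the community moved back toward
  baseline during the phase, and faster or more complete recovery gives
  a strictly larger index.
* **Associations** — beta-diversity shift series (successive-sample or
  from-baseline), per-factor OLS regressions, Spearman and
  point-biserial correlations, and a per-taxon Kruskal–Wallis phase
  screen with Benjamini–Hochberg control.

Data live in an S4 `MicrobiomeExperiment` (a `SummarizedExperiment`
subclass: features × samples counts, metadata in `colData`, taxonomy in
`rowData`), and all tables read/write as strict, validated TSV.

## Worked example

```r
library(microtraj)
res <- runPipeline(defaultRunConfig(seed = 7))

head(res$alpha, 3)
#>   sample_id observed_features chao1 shannon simpson
#> 1    A_D000                34  34.5    2.83   0.787
#> 2    A_D003                30  30.5    2.78   0.782
#> 3    A_D005                32  32.0    2.92   0.798

str(res$permanova$A)
#> List of 5
#>  $ pseudoF      : num 4.01
#>  $ pValue       : num 0.001
#>  $ nPermutations: int 999
#>  $ groupSizes   : int [1:5] 6 6 6 8 27
#>  $ seed         : int 18

print(res$resilience$A, digits = 3)
#>          phase D0    DL    DN  TL  TN        RI flag
#> 1     OnTheWay  0 0.136 0.129  15  29  0.001978
#> 2      Staying  0 0.168 0.174  31 100 -0.000241
#> 3 OnTheWayBack  0 0.147 0.134 103 121  0.002720
#> 4    AfterTrip  0 0.281 0.253 124 135  0.004806
```

Reading the output: each row of `res$alpha` is one swab — for example
sample `A_D000` (host A, day 0) contained 34 distinct ASVs with a
Shannon entropy of 2.83 bits. The PERMANOVA pseudo-F of 4.01 with
p = 0.001 (999 permutations) says host A's community composition
separates strongly by trip phase. In the resilience table, host A
diverges slightly during the Antarctic stay (`RI < 0`: still moving away
from baseline) and recovers fastest after returning home
(`AfterTrip` has the largest index, 0.0048 per day) — while the
`AfterTrip` trajectory values (`DL`, `DN` ≈ 0.25–0.28) remaining above
the `OnTheWay` ones show that recovery is incomplete, matching the
design's ground truth of lasting compositional change.

The taxon phase screen ranks ASVs by how strongly their relative
abundance varies across phases (Kruskal–Wallis H, BH-adjusted q):

```r
head(res$screen, 3)
#>     taxon    H   pValue   qValue
#> 40 ASV076 42.8 1.12e-08 8.38e-07
#> 43 ASV079 31.3 2.64e-06 9.92e-05
#> 63 ASV100 30.2 4.50e-06 1.13e-04
```

Set `outDir` in the config to write every intermediate table plus a JSON
run manifest; re-running with the same config and seed reproduces all
outputs bit-identically.

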