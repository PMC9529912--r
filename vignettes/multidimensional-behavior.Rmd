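---
title: "Multidimensional analysis of behavioral batteries: methods and design"
author: "mdba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional analysis of behavioral batteries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdba)
```

## The problem and the model

Mouse models of neurodevelopmental disorders — the Angelman syndrome
(*Ube3a* m-/p+) mouse being the motivating case — show impairments spread
across many behavioral domains: motor coordination (rotarod), activity (open
field), species-typical behaviors (marble burying, nest building), and
behavioral despair (forced swim). No single test captures the phenotype, and
treatment studies need one number that summarizes *overall* severity.

`mdba` implements a multidimensional analysis of such batteries as a
four-step pipeline:

1. **Standardization.** Every measure is z-scored,
   `z = (value − group mean) / group sd`, so that grams, seconds and counts
   are commensurable. Measures with a significant sex main effect or
   sex-by-genotype interaction (two-way ANOVA screen, `screenSexDependence()`)
   are z-scored *within each sex*, which removes sex differences without
   touching genotype-related structure.
2. **PCA.** Principal components of the column-centered z-matrix
   (`fitBehaviorPCA()`). Because impairments correlate across measures, PC1
   behaves as a composite **severity score**; `orientPC1()` fixes its
   (otherwise arbitrary) sign so that *larger PC1 = more impaired*, using the
   battery's expected impairment directions.
3. **Clustering.** k-means with k = 2 in the space of the first `nPCs` score
   columns (`kmeans2()`).
4. **Validation.** The cluster-to-genotype mapping that maximizes agreement
   is chosen and accuracy is the percent of animals whose mapped cluster
   matches their genotype (`validateClusters()`). Accuracy is therefore at
   least 50% by construction, which is why the false-positive control below
   needs an *empirical* chance band.

The pipeline assumes: a complete-case animals-by-measures table (no
imputation — animals missing any analysis measure are dropped by
`completeCaseSubset()`, mirroring standard practice for these batteries);
exactly two genotype levels for validation (the three-arm treatment workflow
is separate); and measures informative enough that genotype dominates the
leading principal components.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nPCs` | 2 (1 in the treatment workflow) | PCs used for clustering. A scree plot is exported, but the count is a user choice, never auto-selected. |
| `alpha` (sex screen) | 0.05 | two-way ANOVA level; a measure is stratified if the sex main effect *or* the interaction clears it. |
| `alpha` (outliers) | 0.05 | Grubbs' two-sided level, applied once per screened PC column. |
| `nInit` | 50 (10 inside resampling loops) | k-means++ restarts; at these problem sizes 50 restarts make the k = 2 optimum effectively deterministic, while tiny resamples need far fewer. |
| `seed` | — | every stochastic driver is reproducible from one integer seed. |

## Statistical primitives

The screening, post hoc and outlier machinery is implemented in the package
against closed forms, with independent oracles in the test suite:

* **Two-way ANOVA** uses Type II sums of squares by model comparison (each
  main effect adjusted for the other; interaction adjusted for both), the
  conventional choice for unbalanced factorial behavioral data. Balanced
  designs recover the classical decomposition exactly.
* **Tukey's post hoc** test uses the Tukey–Kramer standard error for unequal
  group sizes and the studentized range distribution; tests verify it against
  direct quadrature of the range distribution and note that the adjusted p
  dominates the unadjusted MSE-based (Fisher LSD) comparison, with equality
  at two groups.
* **Fisher's exact test** (used to compare correct/incorrect counts between
  analysis conditions) is two-sided by point-probability summation over the
  margin-fixed hypergeometric support.
* **Grubbs' test** is two-sided:
  `G = max|x − mean|/sd` against
  `G_crit = ((n−1)/√n)·√(t²/(n−2+t²))`, `t` the upper `alpha/(2n)` t-quantile
  with `n−2` df. Outlier screening runs one pass per PC column with no
  iteration — a deliberately conservative rule: removal triggers a single
  re-standardization and re-fit downstream.

## Numerical choices

* PCA is computed by SVD of the centered matrix rather than an explicit
  covariance eigendecomposition (equivalent, numerically stabler). Variance
  fractions are `d_j²/Σd²`.
* Component signs: each column is flipped so its largest-|loading| entry is
  positive (reproducibility); PC1's sign is then overridden by the severity
  orientation. A zero dot product with the impairment directions leaves the
  sign unchanged with a warning.
* k-means ties in the assignment step go to cluster 1; convergence is
  declared when assignments stop changing or the squared centroid shift drops
  below 1e-10; an emptied cluster seizes the point farthest from the other
  centroid. The restart with minimal within-cluster sum of squares wins.
* Accuracy ties between the two cluster-genotype mappings (only possible at
  exactly 50%) resolve to cluster 1 → alphabetically first genotype, for
  determinism.
* Standard deviations use the n−1 denominator throughout.
* z-scoring refuses zero-sd groups loudly; inside bootstrap resamples a
  stratified measure whose per-sex groups are degenerate (< 2 animals of a
  sex, or zero sd) falls back to pooled standardization for that trial, and a
  zero *pooled* sd triggers a redraw. Both events are counted and reported.

## The experiment drivers

* `ablateSingle()` re-runs the pipeline with one measure or one whole test
  removed. The default grid is baseline + one condition per measure + one per
  multi-measure test (11 conditions for the default battery of 8 measures
  from 6 tests); the composition is user-configurable because reasonable
  batteries differ. Conditions are compared to baseline by Fisher's exact
  test on correct/incorrect counts, with no multiplicity correction (one
  planned comparison per condition).
* `scanSubsets()` enumerates every subset of 3..m measures — 219 conditions
  for m = 8 — and summarizes accuracy by subset size. The floor of 3 keeps
  a two-PC analysis non-trivial.
* `partialProfileConditions()` trades measures for animals under block-wise
  missingness: each condition's complete-case set is recomputed, so fewer
  measures generally means more animals.
* `bootstrapCurve()` resamples n animals per genotype *with replacement* and
  re-runs the whole pipeline per resample (duplicated animals count
  separately). The sex-stratification plan is inherited from the full dataset
  rather than re-screened per resample: a two-way ANOVA screen at n = 3 per
  genotype has essentially no power and would only inject noise.
* `falsePositiveControl()` splits a homogeneous (single-genotype) sample into
  random balanced pseudo-groups. Because best-mapping accuracy exceeds 50%
  in finite samples even for pure noise, the no-signal reference is an
  empirical chance band (`nullChanceBand()`): the accuracy distribution of
  k-means on spherical Gaussian data of matched size and dimension. A
  precomputed band for the packaged 36-animal, 2-PC configuration ships in
  `inst/extdata/null_chance_band.json` and is recomputed on the fly for other
  shapes.
* `treatmentAnalysis()` handles the three-arm rescue design (wildtype
  control, mutant control, mutant treatment). Sex screening uses the two
  *control* arms only — the treatment arm must not influence what counts as a
  sex difference — after which all animals share one standardization and one
  PCA. Cluster validation runs on the control arms alone, and the treatment
  effect is a one-way ANOVA plus Tukey contrasts on the severity score (PC1).
* `perCohortRuns()` repeats the pipeline inside each cohort, inheriting the
  full-dataset standardization plan (within-cohort screening at ~14 animals
  per genotype is hopeless), flagging cohorts with fewer than 5 animals per
  genotype.

## The synthetic cohort generator

`generateCohort()` emulates the statistical structure the pipeline assumes,
so every stage is testable without animal data. On a standardized
(unit within-genotype sd) scale, measure *j* of animal *i* is

    z_ij = dir_j·d_j·r_i·mut_i  +  dir_j·a_j·eta_i  +  d_sex_j·(male_i − 1/2)
           +  gamma_{cohort(i),j}  +  sigma_j·eps_ij

with `eta ~ N(0,1)` a shared latent severity factor, `gamma ~ N(0, cohort_sd)`
cohort intercepts, and `r = 1 − rescueFraction` in the treatment arm. Raw
values are `base + scale·z`, clipped to measure bounds and rounded for
integer measures (marbles buried is an integer in 0..20; the immobility and
nest-building scores are percentages). `sigma_j` is derived so the total
within-genotype variance is 1, keeping the configured `d` interpretable as an
empirical Cohen's d; the constructor exposes it for users who want otherwise.

Default genotype effects are calibrated from reported group statistics for
the Angelman mouse battery, converted via `d = t·√(1/n₁ + 1/n₂)` (weight
0.59, open-field distance 1.18, center time 0.18 — effectively null — marble
burying 1.99, forced swim 1.86) and, for measures reported as genotype
main-effect F statistics over repeated sessions, the approximation
`d = 2·√(F/N)` (rotarod 1.20, nest building 1.84); the approximation ignores
the repeated-measures correlation and is documented as such. Sex effects
default to every measure except the two open-field measures (0.8 sd on
weight, 0.5 elsewhere), reflecting the common finding that most of these
assays are sex-dependent while open-field measures are less so; tests never
depend on the exact set. The shared factor loading defaults to 0.25, chosen
once by calibration so that (a) the two-PC pipeline classifies genotype with
roughly 95% accuracy at n = 85 per genotype and (b) PC1 carries 30–45% of
total variance — the regime the method targets. `makeFixtures()` freezes four
fixed-seed datasets shaped like the studies the pipeline is meant for: a
286-animal, 10-cohort dataset in which four cohorts lack weight, open field
and nest building (leaving 170 complete cases), a 12+12 single-cohort
dataset, a 34/25/32 three-arm dataset with a 50% rescue, and 36 wildtype
females for the null control.

**What the generator does not emulate:** raw behavioral time series (rotarod
learning curves, daily nest-building trajectories), floor/ceiling pathologies
beyond simple clipping, heavy-tailed or skewed measurement noise,
batch-by-genotype interactions, and litter structure. Passing tests
therefore demonstrate that the pipeline recovers group structure of the
assumed factor-model form at realistic effect sizes — not that any particular
laboratory dataset will behave identically.

## Problem sizes used by the test suite

The packaged tests run the calibration at 100 synthetic cohorts of 85
animals per genotype, the bootstrap consistency checks at 500 trials per
sample size, the null control at 500 random splits of 36 animals, the
treatment simulation at 100 cohorts of 34/25/32, and the k-means oracle on
200 random instances of up to 10 points — sizes chosen to keep Monte Carlo
error well below the asserted margins while the whole suite stays
interactive.

## Known limitations

* Validation is defined for exactly two genotype levels; multi-group designs
  are supported only through the three-arm treatment workflow.
* Complete-case analysis only; if missingness correlates with severity, the
  complete-case subset is a biased sample and the accuracy estimate inherits
  that bias.
* The severity orientation needs battery impairment directions; a battery
  whose PC1 loadings are orthogonal to the declared directions leaves the
  sign undetermined (warned, not guessed).
* Accuracy is the only separation metric; centroid distance and
  within-cluster spread summaries are plausible extensions, not implemented.
* The bootstrap curve resamples across cohorts and therefore carries
  inter-cohort variability; per-cohort runs typically beat it at matched n,
  and both are reported so users can see the gap.
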