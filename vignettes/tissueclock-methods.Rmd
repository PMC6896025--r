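---
title: "tissueclock: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tissueclock: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `tissueclock`, the
assumptions they make, the tunable parameters and why their defaults are
what they are, what the synthetic data generator does and does not
emulate, and the numerical conventions adopted where the design was
genuinely open.

## 1. The pipeline model

A tissue-specific epigenetic clock is built in five stages, each exposed
as ordinary functions and orchestrated by `run_pipeline()`.

**Harmonization.** Illumina 27K and 450K arrays share a probe subset;
`intersect_platforms()` restricts all inputs to the sorted common probe
set. Probes with 10 or more missing values (per tissue, across all its
samples) are removed — the threshold is strict (`< 10` missing survive) —
and residual missing entries are replaced by the probe's observed mean,
which leaves per-probe means, and hence per-probe regressions, unbiased.
When more than one dataset is merged, each platform batch is
quantile-normalized per probe across samples to the uniform distribution
on [0, 1] (average ranks mapped to `(rank − 1)/(n − 1)`), removing
platform-level distribution shift while preserving within-probe sample
ranks. Whether single-dataset tissues should also be normalized is not
settled; `harmonize(normalize = "auto")` normalizes exactly when more
than one dataset is merged, and the flag accepts `TRUE`/`FALSE` for
either convention.

**Association filter.** For each probe, ordinary least squares of beta
on age; the F statistic `(SST − SSE)/(SSE/(n − 2))` tests a zero slope
and is identical to the squared slope *t* statistic, with p from
F(1, n − 2). This assumes residuals that are approximately normal,
homoscedastic across age, and an age effect that is linear **on the beta
scale** — the same scale the downstream direction analyses use.
Benjamini–Hochberg adjustment is applied over the full family of probes
surviving the missingness filter within one tissue (filter first, test
second); probes with q strictly below the threshold (default 0.05) pass.
No covariates (sex, batch, cell composition) are modelled.

**Stability selection.** The sample columns are resampled with
replacement `n_boot` times (default 500; a resample with zero age
variance is redrawn, and more than 10 % redraws aborts). Each resample
gets an elastic-net fit of age on the FDR-passing probes, and a probe
counts as *present* when its coefficient exceeds 1e−8 in absolute value.
Markers are probes present in **strictly more than** `freq_threshold`
(default 0.95) of the fits. The penalties are tuned once on the full
dataset — `cv.glmnet` over mixing values α ∈ {0.2, 0.5, 0.8} with shared
fold assignments, taking the (α, λ<sub>min</sub>) pair with the lowest
CV error, ties to the smaller α — and then held fixed across all
bootstraps. Fixed penalties are standard practice for stability
selection and roughly 500× cheaper than per-resample tuning; the smaller-α
tie-break prefers ridge-like grouping, which keeps correlated CpGs
together instead of letting the L1 term split their votes. Because
λ<sub>min</sub> optimizes prediction rather than support recovery, the
0.95 threshold is conservative on noisy, normalized, merged data: the
marker lists it returns favour precision (false selections are rare)
over exhaustive recall.

**Clock.** ε-insensitive support vector regression of age on the marker
submatrix (`e1071::svm`). Hyperparameters come from an exhaustive grid —
kernel ∈ {linear, RBF}, C ∈ {0.1, 1, 10, 100}, ε ∈ {0.1, 0.5, 1, 2}
years, and for RBF γ ∈ {1/m, 1/(m·var(X))} — scored by mean CV MAD over
a seeded 10-fold partition, because MAD (years) is the quantity used to
compare clocks throughout. Ties go to the linear kernel, then smaller C,
then smaller ε, then smaller γ, preferring the simplest model. Linear
kernels see raw beta values (coefficients stay interpretable per
beta-unit); for the RBF kernel each marker is standardized with training
statistics stored in the model and re-applied at prediction, so a
serialized model reproduces its predictions exactly.

**Evaluation.** RMSE = √(mean((ŷ−y)²)); MAD = mean |ŷ−y|; Pearson's r
(reported `NA` when either vector is constant); MAPE =
100·mean(|ŷ−y|/|y|) in percent (requires nonzero observed ages);
Theil's U. The U statistic has two textbook variants; `tissueclock`
reports the ratio of the model's RMSE to the RMSE of the naive predictor
that outputs the observed mean age, and tags the value
`"rmse_vs_mean_baseline"` so the convention travels with the number.
U < 1 means the clock beats that baseline.

## 2. Marker characterization

Markers selected by at least two tissue models form the *tissue-common*
group; single-model markers the *tissue-specific* group. The
"two-or-more" reading is the default because the alternative
("three-or-more") leaves markers appearing in exactly two models in
neither group, breaking the partition; `classify_markers(min_common = 3)`
provides the stricter reading for sensitivity analyses.

Directions (*positive/negative ageCGs* — methylation rising or falling
with age) are the sign of the Pearson correlation between **raw** beta
values and age in the tissue where the marker was selected: directions
describe methylation-level change, so they are deliberately not computed
on quantile-normalized values. For common markers the direction is
computed per selecting tissue and the majority sign reported; exact ties
and constant markers are flagged `ambiguous` rather than forced. The
majority rule is a package choice — cross-tissue aggregation has no
single canonical definition.

Enrichment contrasts (island/shore relation, gene-structure class) use
Fisher's exact test. The 2×2 case is computed in-package by
hypergeometric tail enumeration (two-sided, summing all tables with
point probability ≤ observed × (1 + 1e−7), the customary tie tolerance);
implementing it directly keeps the test vectorizable enough that the
suite can verify it *exhaustively* against a brute-force enumeration
oracle over every table with total ≤ 60, and against `stats::fisher.test`
on random tables. Larger r×c tables go through `stats::fisher.test`'s
exact network algorithm, falling back to a seeded Monte-Carlo p-value
(≥ 1e5 draws) when enumeration is infeasible; the method used is
recorded in the result.

Conservation scores (mean phastCons-style score of each probe's region)
are compared between groups with the asymptotic two-sample
Kolmogorov–Smirnov test; `mean_region_conservation()` turns per-base
score vectors into the per-region means when per-base data are
available. The young/old contrast takes the k = 5 oldest and youngest
samples per tissue (ties at the boundary broken by sample ID for
determinism), reports the old-minus-young mean beta difference over the
markers, and flags designs whose age gap is ≤ 40 years, where the
contrast is weakly informative.

## 3. The synthetic generator

`generate_panel()` emulates exactly the structure the pipeline assumes:

- ages uniform over `age_range` (default 20–90 years), matching the
  broad, roughly flat cohort ranges this workflow targets;
- planted probe j in tissue t follows
  `beta = clamp(b0 + s·age + ε, 0, 1)` with ε ~ N(0, `noise_sd`) and
  `s = direction·slope_magnitude` where planted and 0 elsewhere —
  age-linear on the beta scale, because that is the model the
  association test fits. Intercepts are sampled so mean trajectories
  stay at least `3·noise_sd + 0.02` from both boundaries over the age
  range, keeping clamping below ~1 % of entries at defaults;
- common markers keep one direction in all tissues; specific markers
  have nonzero slope in exactly one tissue and are genuine nulls
  elsewhere; positive fractions default to 0.8 (common) and 0.4
  (specific), reproducing the common-group skew toward positive ageCGs;
- annotation: island probability 0.7 / 0.3 / 0.35 for
  common / specific / background probes (non-island mass split evenly
  between shore and other); conservation scores Beta-distributed with
  means 0.6 (common) and 0.5 (specific and background) at concentration
  κ = 10 (sd ≈ 0.15) — a gap and spread at which the KS comparison has
  good power around 100 markers per group, verified by simulation;
- entries masked independently at `missing_rate` (default 1 %); the 27K
  dialect export carries all planted markers plus 80 % of null probes,
  so the two dialect files overlap without being identical;
- defaults: 3 tissues × 150 samples, 2,000 probes, 20 common + 15
  specific markers per tissue, slope 0.005 beta-units/year, noise SD
  0.02 beta-units.

Not emulated, by design: cell-type composition, batch effects beyond
the two platform dialects, genome-realistic probe coordinates or
correlation between neighbouring probes, Infinium I/II chemistry, and
the bimodal marginal distribution of real beta values (null baselines
are uniform on the interior). Gene-structure classes are drawn from one
fixed background distribution for *all* probes, so the gene-structure
background comparison is null-calibrated on synthetic data rather than
enriched. Consequently, passing tests demonstrate that the pipeline
recovers the structure it assumes — linear age signal, planted
annotation differences — not that real tissues satisfy those
assumptions; effect sizes and the noise model are tunable inputs
recorded in the ground truth, not biologically calibrated constants.

## 4. Numerical conventions and degenerate inputs

- Probes constant up to roundoff (SST ≤ 1e−24) get slope 0, F = 0,
  p = 1; a perfect nonzero fit (SSE = 0) gets F = ∞, p = 0.
- `filter_missing(max_missing = 0)` keeps exactly the fully observed
  probes (the strict-`<` rule applies for thresholds ≥ 1).
- Quantile normalization uses average ranks, so constant probes map to a
  constant and re-normalizing a normalized matrix is the identity.
- Elastic-net "present" means |coefficient| > 1e−8; glmnet is given a
  short decreasing λ path ending at the target λ for warm-start
  stability.
- Every stochastic stage takes an explicit seed and restores the
  caller's RNG state; `run_pipeline()` derives per-stage seeds
  deterministically from the master seed and the stage name, and its
  manifest records parameters, seeds, row counts and output checksums,
  so a rerun with the same configuration is checksum-identical.
- The command-line surface is intentionally thin: the package is an R
  analysis library, driven by `run_pipeline()` with a `pipeline_config()`
  (or a YAML/JSON file via `read_pipeline_config()`); there is no
  separate shell binary.

## 5. Problem sizes in the test suite

The suite exercises the statistical claims at sizes chosen to make each
check sharp yet quick: oracle equivalences on ~1,000 random instances
per primitive (and exhaustively for the 2×2 Fisher test up to table
total 60); type-I calibration on 10,000 null probes at n = 100; null
behaviour of the FDR selection over 200 replicate panels;
stability-selection recovery on a 2,000-probe, 30-marker panel at
n = 150 with 100 bootstraps (the bootstrap count is the one scaled-down
parameter relative to the 500-fit default); clock recovery with 200
training and 50 held-out samples; and characterization power over 100
replicate annotation draws at 80–100 markers per group.

## 6. Known limitations

- The association model is age-linear on the beta scale; strongly
  logistic-shaped trajectories lose power and their planted-slope
  recovery guarantees do not apply near the [0, 1] boundaries.
- Stability selection under a prediction-optimal λ is conservative (see
  §1); tissues whose signal survives merging and normalization weakly
  may yield short marker lists, and the common/specific partition
  degrades when per-tissue recall drops.
- The KS comparison uses the asymptotic p-value; for groups of fewer
  than ~10 markers it is unreliable (and the function refuses groups
  smaller than 2).
- MAPE is undefined at observed age 0; newborn cohorts need a different
  relative-error metric.
- Mean imputation shrinks per-probe variance slightly; with the ≥10
  missing-value filter at the default missing rate this is negligible,
  but aggressive missingness would call for a model-based imputer.
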