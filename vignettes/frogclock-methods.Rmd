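---
title: "Methods: cross-species methylation clocks for clawed frogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species methylation clocks for clawed frogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frogclock)
```

`frogclock` implements an end-to-end analysis of aging DNA methylation in the
two laboratory clawed frog species, *Xenopus laevis* and *Xenopus
tropicalis*, optionally combined with a human cohort: cohort QC by
correlation-distance clustering, elastic-net epigenetic clocks under several
species-aware age parameterizations, an epigenome-wide association study
(EWAS) of age with cross-species meta-analysis, and hypergeometric
enrichment of age-related CpGs against annotation sets such as Polycomb
repressive complex 2 (PRC2) targets. This vignette records the models, the
tunable parameters, and the design decisions, in that order.

## Age parameterizations

Clawed frogs mature early relative to their lifespans, and the two species
differ several-fold in both constants (registry defaults: *X. laevis*
lifespan 30.3 y, maturity 1 y; *X. tropicalis* 16 y, 0.375 y; human 122.5 y,
maturity 13.5 y). Methylation drifts quickly through development and slowly
through adulthood, so regressing on raw years wastes resolution where the
data are dense. Three response scales are supported:

* **identity** — chronological age in years; used by the single-species
  clocks, where a common time axis is unproblematic.
* **log-linear** — `F(a) = log((a + k) / (m + k))` for ages up to maturity
  `m`, continuing linearly with matched slope `1/(m + k)` beyond it. The map
  is continuously differentiable, strictly increasing, and exactly
  invertible, so predictions are reported back in years. The offset `k`
  (default `m/5`) bounds the log region at age zero; samples as young as two
  days post-fertilization remain well separated. The human maturity constant
  (13.5 y) only matters for the dual-species chronological clock and is
  configurable in `default_species_registry()`.
* **relative** — age divided by the species maximum lifespan, a
  dimensionless fraction that aligns species with very different lifespans.
  Relative predictions are reported raw, not clipped to [0, 1]: out-of-range
  values are informative about calibration and match how regression output
  is usually displayed.

## Clocks

A clock is a sparse linear model on CpG beta values: elastic net with mixing
parameter fixed at `alpha = 0.5`, penalty chosen by an internal 10-fold
cross-validation minimizing mean squared error on the *transformed* response
scale (the transformed scale is a deliberate choice; the alternative —
minimizing error in years — over-weights the oldest animals). CpGs are first
restricted to those "detectable" in the training samples, defined as mean
beta within (0.05, 0.95) by default; probes saturated at either rail carry
no usable dynamic range. Coefficients are reported on the raw beta scale, so
a fitted clock is one linear formula plus its inverse age transform, and is
serialized as a self-describing text file.

Two numerical details matter for reproducibility. Training samples are
internally sorted into a canonical order before fitting, which makes the fit
exactly invariant to how the input columns were arranged (floating-point
summation order included). And if the inner cross-validation selects the
weakest penalty on glmnet's automatically generated path — which happens for
near-noiseless responses, where the path stops early — the path is extended
toward weaker penalties until the optimum is interior.

Seven canonical specifications are provided (`clock_specs()`): the
two-species pan-tissue clock and its relative-age variant, a young-animal
clock (training restricted to ages below 2 y), one clock per frog species on
raw years, and the two dual-species human–frog clocks (chronological and
relative). Frog-only clocks are evaluated by leave-one-out cross-validation;
the dual clocks, with larger cohorts, use seeded 10-fold cross-validation
stratified by cohort so every fold contains both human and frog samples
(unstratified folds can degenerate at these cohort imbalances). Accuracy is
summarized by the Pearson correlation between out-of-fold predictions and
truth and by the *median* absolute error — robust to the handful of old
outliers these cohorts contain — in years, or in lifespan fractions for
relative clocks.

## EWAS and meta-analysis

Each species is screened separately: per CpG, the Pearson correlation `r`
between beta and age in years, `t = r sqrt(n-2) / sqrt(1-r^2)` against a
Student t distribution with `n - 2` degrees of freedom (two-sided), and a
signed normal-equivalent `z`. Tissue is ignored within a species — at 30–35
samples per species a per-tissue screen is underpowered — but a per-tissue
mode (`split_by_tissue = TRUE`) is available and can be recombined across
tissues with the same meta-analysis operation. Species are combined by
Stouffer's method with equal weights, `z_meta = sum(z_i)/sqrt(k)`. Fixed
reporting thresholds follow genome-scan convention: genome-wide `p < 1e-7`,
suggestive `p < 1e-5`; no further multiplicity adjustment is applied, and
both cutoffs are parameters. P-values are floored at `1e-300` so that
numerically perfect correlations keep finite `z` and remain rankable.
`compare_z()` correlates two z profiles over their CpG intersection, e.g.
against an externally supplied mammalian EWAS of age.

The correlation screen deliberately avoids threaded BLAS matrix products in
favor of plain summation: repeated pipeline runs are byte-identical, which
the multi-threaded reductions do not guarantee.

## Enrichment

From any EWAS or meta table, the top-k (default 500) positively and
negatively age-related CpGs are selected by ranked `z` (ties broken by CpG
id for determinism) and intersected with named annotation sets on an
explicit restricted background — restricting the background to the CpGs the
platform can actually interrogate is what keeps array content from
masquerading as biology. Significance is the one-sided hypergeometric upper
tail; the lower tail is also emitted for depletion readings. The effect size
is the sample odds ratio of the 2x2 table with a Haldane–Anscombe 0.5
correction when a cell is empty (the conditional-MLE estimator would also be
defensible; the sample OR is simpler and reproducible). Gene-regulatory
domain mapping of the GREAT style is out of scope: enrichment runs on
user-supplied CpG-to-set membership only.

## QC clustering

Sample structure is inspected with agglomerative clustering under
`1 - Pearson` correlation distance and average linkage (UPGMA), whose merge
heights are nondecreasing. Cutting the tree at a height (0.29 by default in
the pipeline; a parameter, not a constant) yields branch labels in leaf
order for color bands or outlier review. Missing betas enter correlations
pairwise-complete, consistent with the package-wide missingness policy
(default: drop incomplete CpGs before model fitting, optionally impute by
CpG mean — array studies rarely document this step, so it is explicit and
configurable here). No automatic outlier-exclusion rule is applied; branch
membership is reported and exclusion is left to the analyst.

## The synthetic cohort generator

Because suitable public cross-species array data cannot be assumed, the
generator (`generate_cohort()`) emulates the statistical structure the
analysis relies on, with defaults fixed at the emulated study design
(`default_study_plan()`): 35 *X. laevis* samples (ages 0.005–19 y) and 30
*X. tropicalis* samples (0.005–8 y) across blood, brain, liver, muscle,
skin, toe and whole-animal preparations, plus 200 human samples (ages
0–101 y) for the dual clocks. Betas follow

```
beta = clip01(baseline + species_offset + tissue_offset
              + direction * effect * g(age) + noise)
```

where `g` is the species log-linear transform rescaled to [0, 1] over that
species' planned age range — so the planted signal is monotone but nonlinear
in years, exactly the shape the clocks assume. Defaults: 4000 CpGs, 300
positive and 200 negative age-drifting CpGs, maximum drift 0.35 beta units,
Gaussian noise sd 0.03, per-tissue offsets sd 0.02, species baseline shifts
sd 0.05. Null baselines mix low/intermediate/high Beta distributions
(40/20/40) to mimic array bimodality; planted positive (negative) CpGs start
low (high) so drift rarely clips — the clipping rate is reported and stays
below 5% at defaults. Effect sizes get a mild per-species modulation
(uniform 0.8–1.2), reflecting that age effects are rarely identical across
species. Ages are drawn log-uniformly after shifting by the transform offset
`k`, which over-represents embryos and juveniles as aging-cohort designs do,
and makes an age lower bound of zero valid. 80% of positive CpGs carry the
PRC2 flag against a 10% background rate, mirroring the known PRC2 bias of
age-gaining CpGs; a PRC1 set drawn entirely at background rate serves as a
negative control. A single seeded random stream makes every cohort
bit-reproducible.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: probe-level hybridization artifacts and batch
effects, genomic coordinates and neighborhood correlation among CpGs,
realistic tissue-specific aging rates, and the confounding of whole-animal
samples with young age that a real developmental series has (tissues are
assigned independently of age here precisely so that null screens stay
calibrated). Accuracies obtained on synthetic cohorts demonstrate that the
pipeline recovers structure it is pointed at, not that real frog clocks
reach any particular accuracy.

## Problem sizes and reference checks

The package's own end-to-end checks run the full default design: LOO over
the 65 frog samples for five clocks and 10-fold over all 265 samples for the
two dual clocks, a scale chosen so the complete suite runs in minutes on one
CPU while leaving every code path exercised. `scripts/acceptance.R` repeats
those seven cross-validations from scratch and writes the headline metrics
as JSON. Under the default generator the pan, relative, single-species and
dual clocks comfortably exceed reference accuracies in the R = 0.84–0.96
range; the young-animal clock is the one borderline case, since restricting
to ages below 2 y leaves only ~15% of the transformed age range (and thus of
the planted drift) while the noise floor is unchanged — its out-of-fold R
fluctuates around 0.89–0.93 across seeds. That behavior is a property of the
stated simulation conditions, and the package reports whatever the run
produces rather than retuning the generator around it.

## Known limitations

* Elastic-net clocks inherit glmnet's behavior for `p >> n`; with very few
  samples the inner 10-fold penalty selection becomes noisy (it switches to
  ungrouped CV error estimates below 3 observations per fold).
* The EWAS screen assumes an approximately linear beta–age relationship per
  CpG when assigning significance; strongly sigmoidal drift loses power.
* Stouffer combination weights species equally regardless of sample size;
  that matches the reference procedure but is not efficiency-optimal.
* Enrichment assumes exchangeable CpGs under the null; correlated probes
  (e.g. CpG islands) make the hypergeometric p anti-conservative.
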