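---
title: "Methods: from tray images to selection gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tray images to selection gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotray)
```

phenotray implements the full analysis chain of a factorial
heat-by-drought greenhouse experiment on rosette plants: top-view tray
images are segmented into per-pot rosette areas, area time series are
fitted with a family of growth curves, harvest weights yield leaf and
root functional traits, and a phenotypic selection analysis relates
standardized traits to fitness within each treatment. A synthetic-data
generator produces complete experiments with known ground truth, so
every stage can be validated quantitatively without any external data.

## The experiment being modelled

The design is a 2 x 2 factorial: average vs high temperature crossed
with average vs low watering, giving `control`, `heat`, `drought` and
`heat_drought` cells. Plants come from five populations (one large
central population, two northern and two southern range-edge
populations) with seed families nested inside populations. Each
treatment cell contains spatial blocks, each block holding one replicate
seed per family in 54-pot trays; only every second pot (a checkerboard,
27 per tray) is used, so rosettes never touch and per-pot pixel counting
is unambiguous.

## Imaging: colour-range segmentation and pixel counting

A tray photograph is segmented by keeping pixels whose HSV hue falls
inside a green window *or* inside a red window (the union catches both
healthy and anthocyanin-reddened stressed tissue), subject to minimum
saturation and value so grey background and soil are excluded. The mask
is then summed inside each used pot cell and converted to area with the
square of a single mm-per-pixel calibration scalar per tray.

Numerical conventions that make the counting exact:

* pot cells are half-open pixel rectangles `[x0, x1) x [y0, y1)` in
  0-based coordinates, so the grid tiles the tray with no overlap and no
  double counting;
* unused pots are *absent* from results, never reported as zero;
* missing imaging days leave gaps in a series, never zeros, whereas a
  dead (fully segmented-away) plant genuinely reads zero.

No numeric colour thresholds are inherited from any particular camera:
the windows are configuration (`segmentation_config()`), and the
synthetic fixtures use colours strictly inside/outside the windows so
that tests do not depend on the particular defaults. There is no
exposure normalization and no checkerboard scale detection; calibration
is one scalar per tray.

The synthetic renderer (`render_tray_image()`) draws each plant as a
filled disk centred in its pot cell, sized so that disk area matches the
requested rosette area at the image scale, and returns the *exact* drawn
pixel count per pot. This gives the imaging pipeline a known truth: the
round trip render -> segment -> count must be pixel-exact, and the
area error is pure disk rasterization error, which falls below 5% once
the disk radius reaches about 8 px.

## Growth curves: seven candidates, AIC, three traits

Seven models compete for each plant's area series (t in days from
germination, area in mm^2):

| model            | mean function                         | free parameters |
|------------------|---------------------------------------|-----------------|
| linear           | a + b t                               | 2 |
| exponential      | a e^{bt}                              | 2 |
| power            | a t^b (0 at t = 0)                    | 2 |
| logistic2        | A_max / (1 + e^{(x_mid - t)/scal})    | 2 (A_max fixed at max observed area) |
| logistic3        | A / (1 + e^{(x_mid - t)/scal})        | 3 |
| von Bertalanffy  | A (1 - e^{-k (t - t0)})               | 3 |
| Gompertz         | A e^{-e^{-k (t - Ti)}}                | 3 |

Fitting is Levenberg-Marquardt nonlinear least squares (the linear model
is solved exactly). Starting values are heuristic: asymptote at 1.05 x
the maximum observed area, inflection at the day nearest half-maximum,
scale at a quarter of the observed day range; if the first attempt
fails, three deterministic perturbations (x0.7, x1.4, x0.9) are tried
before the fit is flagged non-converged with an infinite AIC sentinel.

Models are compared within a plant by the Gaussian-NLS criterion
`AIC = n log(RSS/n) + 2 (k + 1)`, counting the error variance as a
parameter and dropping additive constants (identical across models, so
harmless for within-plant comparison). The RSS is floored at 1e-12 so
that noise-free fixtures keep a finite AIC. Near-ties (below 1e-9) go to
the model with fewer parameters, then to a fixed model order.

From the three-parameter logistic fit the three growth traits are
extracted: `size` = A (mm^2), `x_mid` (days to the inflection, i.e.
time of fastest growth) and `growth_rate` = A / (4 scal), the analytic
slope at the inflection (mm^2/day).

Two candidates deserve a note on identifiability. Gompertz and
logistic3 are near-equivalent sigmoids at realistic noise, and a curve
generated from logistic2 *is* a three-parameter logistic mean function
(logistic2 is the A-constrained special case; the fitted logistic2 pins
its asymptote at the noisy observed maximum, so the free-A form usually
fits better). Model-selection power checks therefore count logistic3 and
Gompertz as identifying each other, and logistic3 as identifying
logistic2-truth. The von Bertalanffy generator mapping uses t0 = 0 with
k = log(2)/x_mid so the generated curve is nonnegative over the whole
observation window.

An intrinsic property worth knowing: with the AIC penalty of 2 per
parameter, a spurious extra parameter is admitted with asymptotic
probability P(chi-squared_1 > 2), about 15.7%. Parsimonious truths
(e.g. a purely linear fitness surface or growth curve) are therefore
expected to be identified in about 84% of replicates, not more — this
is a ceiling of AIC itself, not of the implementation.

## Functional traits and nuisance correction

From harvest weights: SLA = rosette area (mm^2) per dry weight of
living leaves (mg); LDMC = dry weight of living leaves (mg) per fresh
weight (g) — note the deliberately mixed units; root:shoot = root dry
weight over the dry weight of all leaves and inflorescences. Dead leaves
are excluded from SLA and LDMC. Whether "all leaves" in the root:shoot
denominator includes dead leaves is ambiguous in common usage; the
package includes them by default with `include_dead_leaves = FALSE` to
restrict to living tissue. The SLA numerator is the rosette area from
the final images (leaf area approximated by rosette surface area).

`growth_rate`, `root_shoot`, `SLA` and `LDMC` are log10-transformed to
approach normality; `size` and `x_mid` are analysed untransformed.

Traits are then screened for nuisance effects — days to germination (a
covariate), block, and tray within block. "Considerable variance" is
operationalized as a per-term one-way ANOVA p < 0.05 (an exposed knob,
`alpha`); each passing term is removed by OLS residualization with the
grand mean re-added, sequentially in the order listed (a joint
residualization is available by flag). Because blocks and trays are
nested inside treatment cells, `build_trait_table()` runs the screening
and residualization separately within each treatment — pooled
correction would absorb the treatment effects themselves.

## Selection analysis

Traits are standardized to mean 0, sd 1 (sample sd) within each
treatment, so coefficients are comparable selection gradients. The
fitness measure differs by cell, because each cell leaves a different
measure informative: flowering propensity under control, survival under
single stress, longevity (days to death or harvest) under combined
stress where almost everything dies.

Because plants that die under combined stress leave no harvest
material, SLA, LDMC and root:shoot in that cell are replaced by family
means: the family's mean under heat and its mean under drought are
averaged; a family present in only one single-stress cell contributes
its single mean (flagged); a family in neither is excluded.

Univariate analysis fits `W ~ z` and `W ~ z + z^2` (the quadratic model
keeps the linear term, the standard hierarchy) and reports the lower-AIC
model with Wald standard errors. Binary fitness uses a logit-link
binomial GLM (iteratively reweighted least squares); longevity uses an
identity-link Gaussian model — the likelihood family for longevity is a
deliberate, configurable choice. Complete separation is detected and
reported as non-estimable rather than as a huge coefficient. The
multivariate model includes all six traits with linear terms only; its
coefficients are the direct (Lande-Arnold) selection gradients.
Quadratic coefficients are reported **as fitted**, not doubled to the
conventional quadratic gradient gamma; double them yourself if you need
that convention.

## Population statistics

* `wilcoxon_rank_sum()` contrasts southern (SE, SW) against
  northern/central (NE, NW, C) populations. For combined group sizes up
  to 12 without ties the two-sided p-value comes from full enumeration
  of all rank splits; otherwise from the normal approximation with
  tie-corrected variance and 0.5 continuity correction. Contrasts are
  plant-level by default (the pooling unit is a documented choice).
  Two-sided p-values throughout, no multiple-testing correction.
* `correlation_matrix()` gives pairwise-complete Pearson correlations
  with t-distribution p-values.
* `pca_per_treatment()` eigen-decomposes the trait correlation matrix;
  eigenvalues sum to the trait count, components are ordered by
  decreasing eigenvalue, and each loading vector is signed so its
  largest-magnitude entry is positive.
* `factorial_effects()` is a deliberately simplified fixed-effects
  estimator (OLS, or logit GLM for binary outcomes) of intercept, heat,
  drought and interaction, where the interaction is the deviation of
  the combined cell from additivity. It validates synthetic
  experiments; it is **not** a mixed-model analysis with random
  population/family structure, which is out of scope.

## The synthetic-data generator

`sim_config()` holds every knob; defaults describe one fixed set of
study conditions:

* growth truth is the three-parameter logistic (the best-supported
  model), with per-treatment means of A around 1465 mm^2 (control)
  falling to about 820 mm^2 under combined stress, x_mid about 27 d
  falling to 22 d, scal about 4 d; a config switch generates from any
  of the seven models for power experiments;
* observation noise is Gaussian, sd 30 mm^2 (2% of the control
  asymptote), imaging every 3.5 days (twice weekly) for 70 days, areas
  clipped at zero and truncated at death;
* mortality before harvest is 3% (control), 13% (heat), 16% (drought)
  and 93% (combined) — worse than additive on the logit scale — with
  the two southern populations given a +2.5 logit survival advantage in
  the combined cell only; day of death follows a geometric hazard over
  imaging steps (no hazard model is prescribed by the design, so the
  simplest memoryless one is used), except under combined stress where
  death day is Gaussian around a linear predictor so longevity carries
  the configured selection signal;
* harvest weights are constructed by inverting the trait definitions
  from per-treatment target SLA/LDMC/root:shoot, with family-level
  random effects (sd 0.05 on the log10 scale) shared across treatments
  and plant-level log10 noise of the same size — within-family trait
  variances are order-of-magnitude choices, not calibrated values; dry
  weights are floored at 0.1 mg so ratios stay positive and
  log-transformable;
* fitness is generated under known selection coefficients `beta` on the
  standardized true traits, applied to each cell's own fitness measure
  (flowering logit in control, survival logit under single stress,
  longevity mean under combined stress);
* the population design keeps all populations in all blocks for balance
  (real designs often under-replicate edge populations across blocks),
  with a default of 20 central vs 3 edge families per population so the
  central population can support selection analysis at desk scale;
* reproducibility: one global seed; every per-plant draw uses a
  substream seed derived from (seed, plant id), so any subset of plants
  regenerates identically.

### What the generator does and does not emulate

It reproduces the design hierarchy, sigmoid growth with observation
noise, censoring by death, stress-dependent and synergistic mortality,
trait-consistent harvest weights, and trait-dependent fitness. It does
**not** emulate realistic leaf shapes (disks suffice for segmentation
testing), overlapping rosettes, lighting or exposure variation, climate
input, or correlated trait evolution across treatments. Passing tests
therefore demonstrate correctness of the computation chain under known
truth — not robustness to messy real photographs.

## Problem sizes used in the test suite

The suite validates: pixel-exact imaging round trips on 20 trays;
exact recovery of noise-free logistic parameters (relative error below
1e-6, growth rate 93.75 mm^2/day for A = 1500, scal = 4);
model-selection power with 200 plants per generating model at 2% noise;
multivariate gradient recovery with beta = (0.6, -0.4, 0, 0, 0, 0) at
n = 2000 over 100 replicates; AIC form choice over 100 replicates;
exhaustive rank-split enumeration up to n = 10 plus a 1000-replicate
null-uniformity check; and the factorial mortality pattern over 10
seeded default experiments. These sizes were chosen as the smallest
that make the binomial success bands meaningful.

## Known limitations

* No mixed-effects growth or trait models (population/family random
  structures); the factorial estimator is fixed-effects only.
* No correlational selection (z_i z_j terms), fitness-surface splines,
  or mean-standardized gradient conversions.
* The imaging module assumes one calibration scalar per tray and
  non-overlapping plants; it performs no instance segmentation.
* Longevity's likelihood family (Gaussian) is an assumption; AIC values
  are not comparable across different fitness measures.
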