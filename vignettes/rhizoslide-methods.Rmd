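---
title: "Methods: imaging, trait extraction and split-nitrogen statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging, trait extraction and split-nitrogen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoslide)
```

This vignette is the package's own account of the methods it implements:
what each model assumes, which parameters matter and why their defaults are
what they are, how the synthetic generators relate to real data, and where
genuinely open design choices were resolved.

## The experimental system

A rhizoslide carries one maize plant per side of a plexiglass sheet covered
with germination paper; roots grow visibly in 2D. A vertical wax barrier
ironed into the paper splits each side into two irrigation compartments, so
one root system experiences high nitrogen on one side of the barrier and
low nitrogen on the other. Cultivation runs 26 days: uniform low-N supply
until day 14 (solution change), then the split application until harvest,
with imaging every second day. The trial layout is a randomized complete
block design — genotypes × 4 replicates, the genotype × replicate
combination identifying one physical slide, each slide contributing a front
and a back plant.

## Dual-illumination fusion

Root photographs are taken twice, lit from the left and from the right LED
bar. Either exposure carries one-sided glare: the background paper is
brightened near the light source and, more damagingly, the dark root signal
is washed out there. Because slide and camera do not move between
exposures, the two frames are pixel-aligned and can be combined by the
per-pixel, per-channel minimum (`fuse_min_tonal()`): the darker rendering of
every pixel survives, which is the root-preserving one. Per-channel (rather
than whole-triple) selection was chosen because glare is not colour-neutral
and channel-wise minima reduce it independently; no registration or
flat-field step is applied, matching the fixed-geometry acquisition.

The fusion operator is an elementwise lattice meet, so it is commutative,
associative, idempotent, and bounded above by both inputs — properties the
test suite checks on random images, alongside a contrast property on
rendered scenes (below).

## Two-step shoot segmentation

Shoots are photographed against a blue board from the side and from the top
(up to four views). Segmentation operates on the excess-green feature map
`f = 2G − R − B`, computed in signed arithmetic (range −510…510, never
wrapped to 8 bits):

1. **Coarse**: `f ≥ 55` (`coarse_segment()`). The high fixed threshold is
   reliable at *finding* plant regions but erodes their borders.
2. **Fine**: Otsu's threshold on the full signed histogram
   (`otsu_segment()`), which recovers accurate region sizes but also admits
   background clutter.
3. **Merge**: keep the coarse regions, enlarged to every 8-connected fine
   component that touches a coarse region or its 8-neighbourhood
   (`merge_segmentations()`); unconnected fine components are dropped.

Numerical choices: Otsu runs on the exact value histogram (no 0–255
rescaling) and breaks ties in the between-class variance toward the lower
threshold; connectivity is 8-way everywhere, the conservative choice for
thin leaf tips; the seed neighbourhood rule (touching *or* 8-adjacent)
covers the case of a coarse mask sitting one pixel inside an anti-aliased
edge — on clean scenes both rules coincide. An optional plant-free
reference image can be subtracted channel-wise before feature mapping;
without one the step is skipped.

The canopy proxy (`canopy_pixel_proxy()`) is the arithmetic mean of the
foreground pixel counts over the available views; any subset of the four
standard views is accepted, since which views exist can vary by station.

## RSML ingestion and root traits

Tracing is done externally (interactive tracing software) and consumed via
RSML. `read_rsml()` converts coordinates to cm — from pixels via the
`resolution` metadata read as mm px⁻¹ (default 0.13, the platform's root
camera), or as-is when the file's unit is cm — preserves the
axile/lateral hierarchy, and computes lateral insertion positions by
arc-length projection of the lateral's base onto the parent polyline. The
coordinate convention is origin at the paper's top-left, x rightward, y
downward, in continuous cm.

Crown roots enter the growth analysis only if they pass
`filter_traceable()`: present at the solution change (or a chosen later
baseline), polyline never crossing the wax barrier x-position, and final
tip at least 0.5 cm (configurable; no canonical value exists) from the
paper's sides and bottom. The rules guarantee that zero measured growth is
biology, not a root running out of paper, and that each root's nitrogen
exposure is unambiguous. A root's compartment is decided by the x-position
of its trace relative to the barrier.

The **branching zone** of a crown root spans from the insertion of the most
distal lateral already present at solution change to that of the most
distal lateral at harvest, measured along the root (the along-root reading
of an ambiguous manual 'ruler' protocol; the choice is recorded here rather
than silently assumed). The zone is halved into two equal-arc-length
segments scored separately (`lateral_metrics()`): lateral count, maximal
lateral length, median lateral length, and count per cm. Two deterministic
conventions replace operator judgement:

* *Median for "medium-sized"*: a human operator traced one representative
  lateral per segment; the package uses the median lateral length (lower of
  the two middle values for even counts), the deterministic statistic
  closest in spirit, recorded in the output as `medlat_rule = "median"`.
* *Boundary tie-break*: a lateral inserted exactly on the segment midpoint
  belongs to the distal segment.

`laterals_in_pre_change_zone()` counts laterals proximal to the zone at
both timepoints, supporting the stasis check that pre-existing root tissue
does not respond to the nitrogen split.

## Linear growth dynamics

Crown-root length and shoot pixel count are modelled as `L(t) = a + b·t`
with `t = 0` at the solution change, by ordinary least squares (`lm()`), so
`b` is the elongation rate and `a` the size at treatment start. Design
choices:

* Pre-treatment observations (`t < 0`) are excluded from root fits by
  default — the line models the response to the split — and can be kept
  with `include_pretreatment = TRUE`.
* No robust or weighted variant: plain OLS, with |studentized residual| > 4
  flagged but never auto-removed.
* Shoot series are truncated at the day leaves outgrow the imaging frame
  (`shoot_cutoff_day`); later counts are censored, not shrunk.
* A root first observed after the solution change yields a slope but no
  intercept: extrapolating `a` backwards past the first observation is not
  defensible and the value is recorded missing.
* Adequacy of linearity is reported through r² only; nonlinear (logistic or
  segmented) growth models are out of scope. For a zero-variance response
  the r² is undefined and returned as `NA` rather than an arbitrary 0 or 1.

## The split-nitrogen mixed model

For split-root traits the model is
`y_ijkl = µ + G_i + N_j + GN_ij + R_k + S_l + GR_ik + ε_ijkl`, with the
genotype × replicate interaction `GR` (the physical slide) random and a
separate residual variance per nitrogen level; per-slide traits (shoot
measures, SPAD) reduce to `y = µ + G + R + ε`. Root traits (`ER_Cr`,
`IC_Cr`, `Med_Lat*`, `Max_Lat*`, `No_Lat*`, `DW_R`) are square-root
transformed before fitting; analyses stay on the transformed scale (BLUPs
and heritabilities are never back-transformed). Branching-zone length,
branching densities and zone start are computed and exported but excluded
from the default model run, as their distributions do not normalise under
the square root.

**Estimation.** Rather than wrapping a general mixed-model engine, the
package implements REML for exactly this model family
(`reml_fit()`): one random intercept factor plus residual strata. The
covariance matrix is block-diagonal in the random factor, so each
likelihood evaluation uses the rank-one Woodbury identity per block and is
linear in the number of observations. Variances are optimized on the log
scale (non-negativity by construction; boundary solutions reported as
exact zeros), with Brent search for one parameter and restarted
Nelder–Mead otherwise, converging the restricted likelihood to a relative
1e-10. Two degenerate cases get closed forms: no random term with a single
stratum (σ̂² = RSS/(n−p)), and a response lying exactly on the fixed-effect
surface (all components zero, OLS coefficients). An independent
cross-check against `nlme::lme` with `varIdent` weights runs in the test
suite; on balanced data the components reproduce the ANOVA
expected-mean-square estimators.

**Inference.** Fixed effects use sum-to-zero coding; each term gets a
marginal Wald F. Denominator degrees of freedom follow the containment
rule: terms constant within slides (G, R) are tested against the slide
stratum, terms varying within slides (N, G:N, S) against the residual
stratum. The reference analysis used a proprietary engine whose default
degrees of freedom are not documented; containment is the closest
published convention and is recorded here as a possible source of small
p-value differences on unbalanced data. Predicted genotype (× nitrogen)
means carry the average standard error of a difference (avsed), from which
Tukey's HSD can be formed as `q·sqrt(MSE/n)` with `MSE = n·avsed²/2`; the
studentized-range quantile `q` is a caller input — its degrees of freedom
are a reporting choice, not something the package should guess.

**Heritability.** `heritability_by_n()` refits each nitrogen level's
records with genotype random (`y = µ + R + S + g + ε`) and forms the
mean-based `H² = σ²_g/(σ²_g + σ²_e/r)` with `r` the number of
replications. Fitting per stratum lets both the genotypic and the residual
variance differ between nitrogen levels, which is the heterogeneous
variance analysis in its simplest faithful form. Negative estimates cannot
occur (log parameterization); boundary zeros give `H² = 0`.

**Diversity summaries.** `genotype_blups()` extracts genotype BLUPs per
trait (genotype random, N/R/S fixed, per-N residuals where applicable);
`blup_summaries()` computes pairwise-complete Pearson correlations and a
PCA by eigendecomposition of the correlation matrix, with each component's
sign fixed by making its largest-magnitude loading positive. BLUPs (not
BLUEs) are the default basis since shrinkage is appropriate for ranking a
diverse panel; fixed-genotype means remain available through
`fit_mixed()`'s predicted means for users who prefer BLUE-based plots.

## What the generators emulate — and what they do not

The synthetic module exists so that every pipeline stage can be exercised
against known truth at desk scale; it deliberately models *appearance and
variance structure*, not root biology (no tropisms, no nutrient fields, no
biophysical growth).

* `render_root_scene()`: dark anti-aliased polyline roots (axiles fanned
  across the paper width, short laterals) on textured bright paper,
  rendered twice with mirrored one-sided glare. Glare both brightens the
  background (gradient strength 40 grey levels at the lit edge) and washes
  out root darkness there (wash fraction 0.9 under full glare) — the
  veiling-reflection failure mode that motivates minimum-tonal fusion; with
  a purely additive gradient the fused image could not beat both inputs in
  global contrast, so a wash term is essential to any faithful scene. Scene
  default 256 × 256 px at 0.13 mm px⁻¹ (desk scale, not full camera
  frames); root strokes ~3 px wide, Gaussian-blurred at σ = 1 px to emulate
  paper texture and anti-aliasing. The matching RSML is written from the
  planted polylines, so trace ingestion can be verified to round-trip arc
  lengths within 1e-6 cm.
* `render_shoot_scene()`: a green stem-and-leaf-strap silhouette
  (RGB ≈ 60/170/60) on the blue board (≈ 30/40/200) with independent
  Gaussian channel noise per view; the exact foreground count per view is
  the truth. At the default noise (σ = 10) the excess-green gap between
  shoot (+220) and background (−330) is tens of noise standard deviations,
  so segmentation should recover areas essentially exactly — the 2 %
  acceptance margin is generous. Real shoots add occlusions, specularities
  and colour gradients that this generator does not model; passing these
  tests validates the segmentation algebra, not field robustness.
* `simulate_growth_series()`: the linear model plus iid Gaussian noise —
  exactly the assumption the growth fit makes, which is the point: it
  yields the analytic sampling distribution the slope-recovery tests
  compare against.
* `simulate_trial()` / `trial_truth()`: the full crossed trial with
  sum-to-zero fixed effects, slide effects `N(0, σ²_GR)`, per-stratum
  residuals, and optional missing-completely-at-random record deletion
  (mirroring roots that never establish; the real missingness mechanism is
  unknown, so MCAR is the default and the rate is a parameter). Defaults in
  `default_trial_config()` put trait means, effect spreads and variance
  components on realistic scales for elongation rates (≈ 1.4 cm d⁻¹, low-N
  deficit 0.35 cm d⁻¹), intercepts (≈ 11 cm) and lateral counts.

## Problem sizes and numerical tolerances

The test battery runs at sizes chosen for exhaustive oracle comparison and
stable Monte-Carlo summaries: 100 random 16 × 16 images for the fusion and
Otsu algebra, 100 random 64 × 64 mask pairs for the merge-vs-flood-fill
equivalence (exact, not approximate), 20 rendered shoot scenes at noise
σ = 10 for proxy recovery, 500 simulated series for slope recovery (bias
< 1 % of the true slope; spread within 10 % of the analytic SE), and 300
simulated 24 × 4 trials for heritability recovery. Mixed-model oracles are
exact-tolerance: F statistics against balanced two-way ANOVA at 1e-8,
variance components against expected-mean-square estimators at 1e-5
relative (the optimizer's practical precision).

One summary-statistic choice deserves a note: in the heritability
asymmetry scenario (genotypic variance present under high N, absent under
low N), the REML estimate of a truly-zero variance component is
boundary-truncated, so its across-simulation *mean* is slightly positive
by construction; the across-simulation *median* is the summary that
reflects the estimator's typical behaviour and is what the asymmetry check
reports (it is exactly zero), alongside the mean for transparency.

## Known limitations

* The mixed-model engine covers one random factor plus residual strata —
  the entire model family used here — and is not a general-purpose REML
  implementation (no crossed random factors, no correlation structures).
* Containment degrees of freedom are exact for balanced designs but
  approximate under missingness; Kenward–Roger-style adjustments are not
  implemented.
* Segmentation is threshold-based and inherits the platform assumptions
  (blue background, green shoots); it is not a general plant segmenter.
* The branching-zone length is measured along the root; if a protocol
  measured straight-line distances the zone bounds would differ slightly
  for curved roots.
* Second-whorl crown roots are carried with their own class label so
  either pooling with the first whorl or separation can be reproduced;
  the default analyses pool them.
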