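---
title: "Voxel-wise grey-matter analysis: models, calibration and design choices"
author: "vbmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise grey-matter analysis: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vbmtools` analyses cohorts of modulated, smoothed grey-matter (GM) density
volumes in a common template space — the standard product of a
voxel-based-morphometry (VBM) preprocessing chain (segmentation, nonlinear
registration, Jacobian modulation, Gaussian smoothing). The package starts
where preprocessing ends: it consumes per-subject NIfTI volumes plus a
subject table, and provides four inference stages used to characterise
grey-matter pathology in a patient group against controls — here motivated
by early Parkinson's disease (PD), where focal amygdala density loss,
altered limbic structural covariance and accelerated age-related decline
are the phenomena of interest.

## The models

### Voxel-wise group GLM with permutation cluster-extent FWE

At every in-mask voxel the GM density is modelled by ordinary least squares
on an intercept, a 0/1 group indicator (control = 0, pd = 1) and nuisance
covariates (age, sex by default):

$$ y_v = \beta_0 + \beta_g\,\mathrm{group} + \beta_a\,\mathrm{age} +
   \beta_s\,\mathrm{sex} + \varepsilon_v . $$

The reported map is the t statistic of the *deficit* contrast
(control − pd), so grey-matter loss in patients appears as positive t.
Family-wise error over the whole map is controlled by cluster extent: the
map is thresholded at a predefined cluster-forming cutoff (default
`t > 4`), and each suprathreshold cluster's size is referred to the
permutation distribution of the *maximal* cluster size obtained by
shuffling group labels. The corrected p uses the add-one estimator
$(1 + \#\{\text{null} \ge s\})/(B+1)$, which can never report zero and is
valid for any number of permutations. When the number of distinct
relabelings is no larger than the requested `n_perm`, the null is
enumerated exhaustively instead and p becomes the exact enumeration
fraction.

Permutations shuffle the group column only, keeping each subject's
covariate row attached to their data. Under the null hypothesis of no
group effect with exchangeable errors this is a valid scheme; more
elaborate covariate-residualisation schemes (Freedman–Lane) address
non-exchangeability induced by strong covariate effects and are out of
scope here. `n_perm` defaults to 5000, giving corrected-p resolution
2×10⁻⁴; calibration experiments in the test-suite use a few hundred
permutations, which is ample to decide significance at α = 0.05.

A deliberately liberal companion, `uncorrected_tmap()`, reproduces the
common uncorrected sanity check (|t| > 2.8 *and* two-sided p < 0.005,
whichever is stricter at the design's degrees of freedom) and flags every
cluster it reports as `"uncorrected"`.

### The group-interaction regression

Both the covariance and the brain-ageing stages rest on one regression,
fitted per voxel:

$$ Y = a + b\,X + c\,\mathrm{PD} + d\,\mathrm{PD}\cdot X + e , $$

with PD the 0/1 group indicator. In *covariance mode* Y is the mean GM
density of a seed region and X the local GM density of the voxel; in *age
mode* Y is the local GM density and X the subject's age. Y and X are
z-scored within each group before fitting ("normalisation"). Because the
group dummy saturates a per-group intercept and slope, the least-squares
solution coincides with two independent within-group simple regressions
with a pooled residual variance — `fit_interaction()` exploits this to
solve the model in closed form, vectorised over voxels, and the test-suite
verifies the equivalence against `lm()` on the z-scored design.

Under within-group z-scoring, the coefficients become interpretable:
$\hat b$ **is** the control-group Pearson correlation (identically, to
machine precision), $\hat b + \hat d$ the patient-group correlation, and
$\hat d$ their difference. $t_d = \hat d / \mathrm{se}(\hat d)$ with
$n - 4$ degrees of freedom tests for a group difference in the X–Y
coupling — a covariance difference in covariance mode, an age-slope
difference in age mode.

### Structural covariance maps

Within one group, the seed covariance map is the across-subject Pearson
correlation between the seed-region mean and every voxel. The default
display threshold is the very strict fixed cutoff p < 6×10⁻⁸ commonly used
to sparsify such maps; BH-FDR is available as the principled alternative
(`method = "fdr"`), since a fixed cutoff is a display convention, not an
error-rate guarantee. For unbalanced cohorts, `balanced_subsample()` draws
the larger group down to the smaller group's size uniformly without
replacement, and `average_covariance_map()` averages the per-voxel r over
(by default) 100 repeats, removing the sample-size asymmetry from visual
comparison.

### Cross-sectional brain ageing

Age-related GM change cannot be measured from cross-sectional data as a
true atrophy rate, but the per-group OLS slope of GM on age (GM-units per
year) is a standard cross-sectional estimate of the predicted rate of
decline. Two parallel fits are kept deliberately:

* the **natural-unit** reduced model (`age_slope_map()`), whose slopes are
  reported in thousandths per year and feed the thresholded difference
  map; and
* the **normalised** interaction model (`age_interaction_test()`), whose
  $t_d$ provides the significance test, optionally FDR-corrected within a
  small-volume mask.

This dual-fit design reconciles unit-free testing with interpretable
rates: the normalised fit's $t_d$ is invariant to per-group affine
rescaling of GM, while the natural-unit slopes carry units a reader can
compare across studies.

The difference map is reported as control slope − pd slope, so *positive*
values mean extra decline in patients. Thresholding uses the absolute
difference (default 0.002 GM-units/year) with the sign preserved in the
output, followed by removal of connected components smaller than 20 voxels
under 26-neighbour connectivity — the conventional operating point for
such maps.

### Clinical association

Clinical scores are collected per visit; the value used for a subject is
the one from the visit nearest in time to the MRI scan. Ties between an
earlier and a later visit resolve to the earlier one, whose data cannot be
contaminated by post-scan disease progression. A missing value at the
chosen visit is filled backward from the most recent earlier visit only —
never forward — and cells that remain unfilled are marked `missing` and
excluded (with a logged count) from association. Association is Pearson
correlation with a parametric two-sided p, and an age/sex-adjusted OLS of
the ROI mean on score + age + sex; the group analysed defaults to patients
only. Provenance (`nearest_visit`, `filled_most_recent`, `missing`) is
recorded for every cell, making the matching step fully auditable and
deterministic.

## The synthetic cohort generator

`generate_cohort()` builds phantoms with exactly the statistical structure
the four stages assume, so that every stage can be calibrated end to end:

* a spherical brain (radius 13 voxels on a 32×32×32 grid of 2 mm voxels)
  with baseline GM density 0.55;
* a focal **atrophy** sphere whose density is reduced by a group effect
  (default 8 % of baseline) in patients — this sphere doubles as the
  covariance **seed**, mimicking a seed extracted from the group VBM
  result;
* an **age-slope** sphere with group-specific linear decline (defaults
  −0.001234 and −0.004434 GM-units/year for controls and patients, the
  magnitudes reported for hippocampal decline in the motivating
  literature);
* a **covariance network** sphere: seed and network voxels share a
  standard-normal latent factor scaled by a per-group loading (defaults
  0.6 vs 0.0) — the simplest construction with a controllable group
  difference in correlation, which is precisely what the interaction term
  $d$ tests;
* i.i.d. Gaussian voxel noise (sd 0.35 before smoothing), then isotropic
  Gaussian smoothing with σ = 3 mm, then clipping at zero — mirroring the
  segment → modulate → smooth order of VBM preprocessing. After smoothing
  the across-subject voxel noise sd is ≈ 0.024, a realistic value for
  smoothed modulated GM maps.

Ages are uniform on [45, 80] (approximating the motivating cohort's means
± SD), sex is drawn at a 0.64 male fraction, and clinical scores are
generated as linear functions of the *measured* seed-region GM with a
requested marginal correlation (defaults: HVLT +0.155, MDS-UPDRS I −0.111,
SCOPA-AUT −0.15, others 0), two visits per subject, visit-level noise and
5 % missingness. The truth record returned with every cohort stores all
planted parameters and region masks, so tests can score recovery (e.g.
Dice overlap between detected clusters and the planted sphere).

Geometry choices worth recording: the three effect spheres are positioned
with at least 3.6 voxels between their surfaces (≥ 2.4 smoothing sigmas),
so planted effects do not bleed into each other's regions; the age-slope
sphere has radius 5 voxels — large enough relative to the 1.5-voxel
smoothing sigma that the planted slope difference keeps a suprathreshold
plateau at the 0.002/year cutoff; and the latent-factor amplitude (0.05 GM
units) was set so the planted control-group seed–network correlation is
≈ 0.6, matching the loading's nominal value. Smoothing attenuates any
in-region step by the region mean of the smoothed indicator (≈ 0.65 for
the age sphere, ≈ 0.75 at the sphere centres); recovery tests therefore
compare estimates against the *attenuated* planted values, which is what
the smoothed data actually contain.

What the generator does **not** emulate: anatomically realistic templates,
registration error, multi-site scanner effects, spatially correlated
subject-level noise beyond the smoothing kernel, lesions, or non-linear
age trajectories. Passing tests on these phantoms therefore demonstrates
the *statistical machinery* — error-rate calibration, oracle equivalence,
planted-effect recovery — not robustness to real-data artefacts.

## Numerical choices

* **Smoothing** is separable convolution with circulant (wrap-around)
  1-D Gaussian kernel matrices. Circular boundary handling conserves the
  image sum exactly, and for a brain phantom centred in the grid the
  wrap-around tails are negligible. The FFT implementation used as a test
  oracle agrees to 10⁻¹⁰.
* **Connected components** (6/18/26-connectivity) are computed on the
  suprathreshold voxel adjacency graph; peak ties within a cluster break
  toward the smallest linear index, and equal-size clusters order by their
  first voxel, so outputs are deterministic.
* **Zero-variance voxels** (possible at mask edges after clipping) get
  t = 0 / r = 0 and a flag; flagged voxels are excluded from multiplicity
  correction rather than silently contributing p = 1.
* **Cluster-forming thresholds are strict inequalities** (`> t`); the
  slope-difference cutoff is inclusive (`≥ cutoff`), implemented as a
  strict threshold at `cutoff·(1 − 1e−12)`.
* **Exhaustive enumeration** replaces random permutation whenever
  $\binom{n}{n_1} \le$ `n_perm`, and the corrected p then becomes the
  exact fraction over all relabelings (the identity labelling included).
* All randomness flows from explicit seeds: the generator's seed is part
  of its config, subsampling and permutation take `seed` arguments, and
  the pipeline expands one master seed into fixed per-stage seeds, making
  the end-to-end report byte-reproducible.

## Problem sizes used by the validation suite

The test-suite calibrates error rates and recovery at sizes chosen to make
Monte-Carlo error small while keeping a desk-scale footprint: 200 null
cohorts of 20+20 subjects for family-wise-error calibration (199
permutations each), 100 cohorts of 50+100 for planted-atrophy detection
(99 permutations), 100 cohorts of 170+170 for slope recovery, 100+100
ROI-level simulations at n = 172 per group for interaction power and size,
and 300 mixed null/alternative sets for FDR control. Interaction
power/size runs on the generator's ROI-level latent-factor simulator
(`simulate_covariance_rois()`), which is the same generative model at
region granularity; the volumetric path for covariance is exercised by the
generator tests and the end-to-end pipeline test.

## Known limitations

* The permutation scheme assumes exchangeable errors under the null; with
  strong covariate effects and unbalanced groups a residualisation scheme
  would be preferable.
* The per-group-normalised interaction test is *conservative* when the
  common within-group correlation is high: z-scoring Y within group makes
  the pooled residual variance scale with $(1 - r^2)$ while the sampling
  variance of a correlation difference scales with $(1 - r^2)^2$, so $t_d$
  is deflated by roughly $1/\sqrt{1 - r^2}$. At independence the test is
  exactly sized; at high common correlation its true level falls well
  below the nominal one. It never over-rejects, so reported covariance
  differences are, if anything, understated.
* Cluster-extent FWE with small degrees of freedom is mildly conservative
  because maximal cluster sizes are small discrete integers: ties in the
  permutation null make the attainable corrected p jump past the nominal
  level.
* Cross-sectional age slopes are predictions of decline, not measured
  atrophy rates; cohort effects are indistinguishable from ageing.
* The fixed covariance display threshold (6×10⁻⁸) is a convention; use the
  FDR branch for defensible inference.
* Parametric p-values for r and $t_d$ assume approximate normality of the
  (smoothed) GM densities; the permutation branch of the interaction map
  avoids this assumption where it matters.
* `load_cohort()` requires all volumes on the mask's grid; registration
  and resampling belong to the upstream preprocessing chain and are out of
  scope.
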