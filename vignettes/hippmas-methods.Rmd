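---
title: "Multi-atlas hippocampus segmentation and volumetric diagnostics: methods"
author: "hippmas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas hippocampus segmentation and volumetric diagnostics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hippocampal atrophy is a supportive imaging feature for the diagnosis of
probable Alzheimer's disease, but manual hippocampus tracing on T1-weighted
MRI is slow and rater-dependent. `hippmas` implements a fully automated
multi-atlas segmentation pipeline combined with voxel-wise machine learning,
plus the volumetric statistics needed to turn segmented volumes into a
diagnostic marker: precision analysis from screening/repeat scan pairs,
linear age detrending, ROC/AUC analysis of CTRL-AD and CTRL-MCI
discrimination, Kruskal-Wallis group tests and a three-class Naive Bayes
benchmark.

Everything runs on synthetic 3D phantoms shipped with the package, so the
entire pipeline is testable on a laptop without access to any imaging
repository.

## The segmentation model

Segmentation proceeds in three phases.

**Phase 1 — spatial normalization.** Every scan is min-max normalized to
[0, 1] (a constant image maps to zeros, so degenerate inputs cannot poison a
pipeline). A smooth multiplicative bias field is then estimated as a
polynomial (total degree 2 by default) fitted by least squares to the
log-intensities of foreground voxels and divided out. Foreground is
`intensity > 0.05`: with noisy acquisitions the background is not exactly
zero, and near-zero voxels otherwise dominate a log-domain fit. This is a
deliberately simple stand-in for full histogram-sharpening bias correction:
any anatomy with low-frequency structure leaks slightly into the polynomial,
the standard trade-off of this family of corrections. A data-driven template
is built by iterated registration and averaging of the (control) training
scans (2 iterations by default; the initial reference is the voxelwise mean
after rigid alignment to the first scan). Registration is an in-package
multi-resolution (3 levels) Nelder-Mead minimization of the mean squared
intensity difference over a 12-parameter affine map, staged as translation,
then rigid, then full affine; a demons-style diffusion-regularized
refinement is available (`register_nonlinear()`, off by default — the
phantom's pose variability is affine). Transforms use the *pull* convention:
they map fixed-space (template) voxel coordinates to moving-space
coordinates, which is the natural direction for resampling. The affine
registration layer is deliberately pluggable: an externally computed
transform can be wrapped in `affine3d()` and used everywhere a recovered one
would be.

**Phase 2 — VOI and atlas selection.** Warped training labels define a
voxelwise hippocampus probability map; the peri-hippocampal volume of
interest (VOI) is the bounding box of its support padded by 2 voxels,
clipped to the grid — every training hippocampus is contained within it by
construction. Left and right hippocampi get separate VOIs and are processed
independently end to end, because volumes are reported per side throughout.
For a test scan, candidate atlases are ranked by the Pearson correlation `r`
between the test and atlas VOI intensity vectors (the classical
product-moment form, computed over the `N` VOI voxels in fixed raster
order), and the 10 highest-correlation atlases are selected.

**Phase 3 — voxel classification and label fusion.** From every VOI voxel a
37-dimensional feature vector is extracted: central moments (mean,
population SD, skewness, excess kurtosis) on cubic boxes of edge 3-9 with
mirror padding at the VOI boundary; five Haralick statistics (energy,
contrast, correlation, inverse-difference-moment homogeneity, entropy in
nats) from symmetric grey-level co-occurrence matrices accumulated per
offset over the 13 unique 3D unit offsets in a 5-voxel patch (8 equal-width
grey levels quantized over the whole VOI so GLCMs are comparable across
voxels), averaged over offsets; and Haar-like box responses (half-box mean
differences along each axis plus a centre-minus-surround contrast, boundary
boxes clipped and normalized by their actual voxel counts) on edges 3-9,
computed from an integral volume. Feature columns are z-scored with
statistics accumulated from the training VOIs only and frozen; zero-variance
columns are dropped and recorded. Before feature extraction each scan's VOI
intensities are additionally standardized to zero mean / unit variance
within the VOI (`standardize_voi`): per-scan brightness and contrast
differences survive global normalization and bias correction, and without
this step sharp per-atlas classifiers misfire on scans whose intensity
scale drifts by a few percent — the usual MRI intensity-standardization
argument.

One feed-forward network per atlas (one hidden layer of 10 sigmoid units,
sigmoid output) is trained by minibatch stochastic gradient descent on the
log-loss to separate hippocampus from background voxels. Background
dominates the VOI (prior around 0.2), so the majority class is subsampled to
a 1:1 ratio per atlas (seeded). The default learning rate 0.1, 100 epochs
and minibatch 32 were calibrated so the networks reach a sharp decision
surface on VOI-sized training sets (of order 10^4 voxels); smaller rates
leave the networks visibly undertrained (soft scores, inflated
segmentations). All training is bit-reproducible given the seed.

A test voxel's score is the correlation-weighted average of the selected
atlas networks' outputs (weights normalized to sum 1; atlases with
non-positive correlation are excluded, keeping the fusion convex). The
binarization threshold is the Bayesian posterior

> t = S P(H) / (S P(H) + (1 - s)(1 - P(H)))

where `P(H)` is the prior probability that a VOI voxel is hippocampal (mean
in-VOI label fraction over training scans) and `S`, `s` are the training
sensitivity and specificity estimated by repeated stratified 5-fold
cross-validation (10 repeats by default) on the pooled training voxels,
capped at 6000 balanced samples to bound the cross-validation cost. A voxel
is assigned to the hippocampus when its fused score strictly exceeds `t`.
Volumes are measured in template space by default (voxel count times voxel
volume); `native = TRUE` additionally maps each mask through the inverse
affine and measures it on the native grid.

## The diagnostic model

Measured volumes carry a normal-aging trend. On control subjects the
package fits, by ordinary least squares,

> V_hat = V0 + k (t - t0),

with `t0` the minimum age of the whole cohort; the reference synthetic
conditions use intercept `V0 = 3173.0` mm^3 and slope `k = -29.9` mm^3 per
year. The *effective* volume is the atrophy deficit

> V_eff = V_hat(age) - V,

exactly in this orientation: `V_eff` is 0 on the model line and grows with
atrophy, so it is used directly as the disease-positive ROC score (for raw
volumes, `-V` plays that role). The ROC curve is a threshold sweep with the
strict "exceeds" rule; the reported AUC is the normalized Mann-Whitney
statistic (ties half-weighted), which equals the trapezoidal area of the
swept curve. Its uncertainty comes from the closed-form Hanley-McNeil
standard error and, optionally, a class-stratified bootstrap (500
replicates by default). Group location differences use the tie-corrected
Kruskal-Wallis chi-square approximation (`stats::kruskal.test`); exact
small-sample p-values are out of scope. The three-class benchmark is a
Gaussian Naive Bayes (`e1071::naiveBayes`) under repeated stratified
10-fold cross-validation (100 rounds by default), with accuracy counted
over CTRL/MCI/AD and sensitivity/specificity treating AD as positive
against MCI + CTRL. Sample (n-1) standard deviations are used throughout
the diagnostics layer, as the context is inferential.

## What the synthetic generator emulates

`make_phantom()` produces a 64^3, 1 mm isotropic T1-like phantom: a
three-tissue brain ellipsoid (cortical shell 0.45, inner white matter 0.65,
ventricle 0.2) with two bent-ellipsoid hippocampi (intensity 0.9) of
controlled volume — an ellipsoid elongated along the anterior-posterior
axis, sheared toward the midline with a unit-Jacobian bend so the target
volume is preserved analytically. Defaults: target volume 2650.2 mm^3 (the
mean training hippocampal volume of the reference conditions), smooth
multiplicative bias of relative amplitude 0.1, additive Gaussian noise
sd 0.02, and a random *rigid* pose jitter (up to 3 voxels translation, 5
degrees rotation). Jitter is rigid rather than full affine so the
ground-truth mask volume is preserved up to voxelization; anatomical size
variability enters through per-subject target volumes instead. The 64^3
grid (not an MRI-native 256^3) keeps a full 10-atlas training plus 5-subject
segmentation run in minutes on one CPU.

`make_cohort()` and `make_longitudinal()` generate the statistical layer:
group sizes 145/217/94 (CTRL/MCI/AD) with ages 73±6, 75±9, 75±9 years
truncated to 55-95; true volume `V0 + k(age - t0)` minus a group atrophy
offset (defaults Δ_MCI = 250, Δ_AD = 500 mm^3) plus a subject random effect
(sd 150 mm^3); measured volume adds per-scan noise of sd 84.3/sqrt(2) mm^3,
so screening-repeat residuals have the reference precision sd of 84.3 mm^3.
Right volumes sit 60 mm^3 above left ones (the direction reported in
clinical cohorts). Screening and repeat scans share the same true volume;
12- and 24-month follow-ups subtract a group-specific annual atrophy
(defaults 30/60/100 mm^3/yr for CTRL/MCI/AD — the control value matches the
normal-aging slope, the patient values are field-realistic choices made
once and kept).

What the phantoms do *not* emulate: anatomical shape realism, Rician noise,
partial-volume mixtures beyond interpolation, multi-tissue texture, or
non-affine anatomical variability. Passing the end-to-end tests therefore
shows the machinery is correct and internally calibrated, not that the
pipeline reaches any particular accuracy on real MRI.

## Numerical choices and edge cases

* Masks loaded from NIfTI binarize at > 0.5 (tolerates interpolated warped
  labels); mask resampling is nearest-neighbour.
* A constant image normalizes to zeros; constant patches return 0 skewness
  and kurtosis; a constant GLCM patch has correlation 0 by convention.
* Population variance in the moment features (deterministic for tiny
  boxes); sample variance everywhere in the diagnostics layer.
* Pearson correlation requires non-constant vectors and errors otherwise;
  ranking ties keep input order.
* `bayes_threshold()` errors on the degenerate denominator
  (`S P(H) = 0` with `s = 1`); binarization is strictly `score > t`.
* Registration non-convergence (iteration cap) is flagged on the result,
  not raised, so batch runs can triage.
* Both-empty masks have Dice 1.
* Template building with a single scan returns that scan unchanged.

## Design choices where the design was open

* The VOI is a padded bounding box of the label-probability support rather
  than a shape-analysis region: it satisfies the containment contract, is
  exactly testable, and keeps the feature matrix rectangular.
* "Other central moments" is fixed to standardized orders 3 and 4; the
  Haralick set is the five canonical statistics, offset-averaged, recorded
  in the schema so it can be extended.
* One network per atlas (not one global classifier): scoring averages the
  selected models with correlation weights, which is what makes atlas
  selection consequential at test time.
* Fusion weights are the raw positive correlations normalized to sum 1.
* Volumes default to template space; the native-space option exists because
  either convention is defensible and the difference is the affine
  determinant.
* Cross-validation sensitivity/specificity is computed on the pooled
  (capped, balanced) training voxels rather than per atlas: `t` calibrates
  the *fused* score, and the pooled estimate is the natural match.
* Problem sizes used by the shipped tests — 10 training atlases, 5 test
  subjects, 64^3 grids, 100-replicate cohort simulations — were chosen as
  the smallest sizes at which the statistical checks are stable.

## Known limitations

* The bias-correction, registration and VOI components are simplified
  stand-ins adequate for template-space phantom pipelines, not
  re-implementations of the clinical tools they replace.
* Affine-only default registration cannot absorb non-linear anatomical
  variability; on real data the demons refinement (or an external
  registration backend via `affine3d()`/`disp_field()`) would be needed.
* The AUC values reported on synthetic cohorts depend on the generator's
  atrophy offsets and are not comparable to clinical AUCs.
* Longitudinal modelling (atrophy-rate estimation, conversion prediction)
  is out of scope; follow-up time points exist to exercise precision and
  correlation analyses.
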