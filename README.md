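# hippmas

Multi-atlas hippocampus segmentation and volumetric diagnostics for
T1-weighted brain MRI, with a synthetic phantom generator that makes the
whole pipeline runnable and testable without any imaging download.

`hippmas` is aimed at neuroimaging methodologists who want a compact,
fully scripted implementation of the classical multi-atlas +
machine-learning segmentation recipe and of the volumetric statistics used
to evaluate hippocampal atrophy as an Alzheimer's disease marker.

## The method

**Segmentation.** Scans are min-max normalized, corrected for a smooth
multiplicative bias field (log-domain polynomial fit), and registered to a
data-driven template built by iterated affine registration and averaging of
the training scans. Warped training labels trace a peri-hippocampal volume
of interest (VOI) per hemisphere. For a test scan, training atlases are
ranked by the Pearson correlation *r* of their VOI intensity vectors with
the test scan and the 10 most similar are kept. Every VOI voxel is described
by 37 statistical and textural features (central moments on 3–9 voxel
boxes, Haralick grey-level co-occurrence statistics, Haar-like box
responses); one 10-neuron single-hidden-layer sigmoid network per atlas,
trained by minibatch backpropagation, scores each voxel, and the per-atlas
scores are fused by a correlation-weighted average. The fused map is
binarized at the Bayesian posterior threshold

    t = S·P(H) / (S·P(H) + (1 − s)·(1 − P(H)))

where `P(H)` is the prior fraction of hippocampal voxels in the VOI and
`S`, `s` are the cross-validated training sensitivity and specificity.
Volumes are voxel counts times voxel volume (mm³).

**Diagnostics.** Segmentation precision is the standard deviation σ of
`V_screening − V_repeat` residuals from same-subject scan pairs acquired
weeks apart. Normal aging is removed with a control-cohort linear model
`V̂ = V0 + k·(t − t0)`; the *effective volume* `V_eff = V̂ − V` (an atrophy
deficit) is the ROC score for CTRL–AD and CTRL–MCI discrimination, with
Hanley–McNeil and bootstrap standard errors on the AUC, Kruskal–Wallis
group tests, and a Gaussian Naive Bayes three-class benchmark under
repeated 10-fold cross-validation.

## Worked example

Generate a synthetic longitudinal cohort whose volumes follow the control
aging line `V0 = 3173.0` mm³, `k = −29.9` mm³/yr with group atrophy offsets
(CTRL/MCI/AD sizes 145/217/94), then run the full diagnostics layer:

```r
library(hippmas)

cohort <- make_longitudinal(cohort_spec(seed = 1))
report <- cohort_report(cohort, n_boot = 500, nb_rounds = 100, seed = 1)
report
#> <precision_report> n=912 pairs: residuals -3.9 +- 87.5 mm^3 (3.3% of 2650 mm^3), H0 mean=0 p=0.176
#> <aging_model left> V_hat = 3155.3 -28.9 (t - 56) mm^3, 95% CI(k) [-34.6, -23.2], R^2 = 0.415, n = 145
#> <aging_model right> V_hat = 3228.9 -29.3 (t - 56) mm^3, 95% CI(k) [-34.4, -24.3], R^2 = 0.480, n = 145
#> AUC (detrended volumes, side-averaged):
#>   timepoint     task   auc   se_hm se_boot
#> 1 screening  CTRL-AD 0.987 0.00847 0.00548
#> 2 screening CTRL-MCI 0.875 0.01790 0.01789
#> ...
#> Kruskal-Wallis (screening): left H=161.3 p=9.2e-36 | right H=168.5 p=2.6e-37
```

The precision block recovers the generator's measurement noise (residual
sd ≈ 84 mm³, ~3% of the 2650 mm³ reference volume); the aging models
recover the generating slope within their confidence intervals; AD
separates from controls more strongly than MCI does, mirroring the larger
atrophy offset.

Segmentation end to end on phantoms (about 6–8 minutes on one CPU):

```r
atlases <- lapply(1:10, function(i) {
  vols <- withr::with_seed(100 + i, rnorm(2, 2650.2, 150))
  make_phantom(phantom_spec(volume_left = vols[1], volume_right = vols[2],
                            seed = 100 + i))
})
aset <- train_atlas_set(lapply(atlases, `[[`, "image"),
                        lapply(atlases, `[[`, "mask_left"),
                        lapply(atlases, `[[`, "mask_right"), seed = 1)

test <- make_phantom(phantom_spec(seed = 991))
res <- segment_subject(test$image, aset, native = TRUE)
tidy(res)
dice(res$left$mask_native, test$mask_left)
#> ~0.92 against the generator's ground-truth mask
```

A shell entry point wrapping the same stages
(`simulate | template | train | segment | diagnose`) is installed at
`inst/cli/hippmas`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/hippmas", package="hippmas"))') \
    simulate --out run1 --seed 1
```

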