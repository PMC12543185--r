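# lamsal — laminar VASO fMRI analysis of visual saliency

Where in cortical depth does a visual saliency signal arise, and how does it
travel between areas? Laminar cerebral-blood-volume (VASO) fMRI can ask this
question because CBV-weighted responses localize to the microvasculature of
individual cortical layers, but the analysis chain is long: paired
nulled/not-nulled acquisitions must be BOLD-corrected, voxel responses
unmixed into layer responses through partial-volume weights, normalized
across subjects, contrasted between orientation-contrast conditions, related
to behavioral contrast sensitivity, and fed into layer-resolved connectivity
and visual-field reconstructions. `lamsal` implements that chain end to end
in R, together with a synthetic-data module that simulates every input with
known ground truth so each stage is validated by parameter recovery.

It is aimed at laminar-fMRI methodologists and at readers who want to
reproduce, probe, or extend the saliency analysis on simulated or deposited
per-participant data.

## The core quantities

- **BOLD correction (BOCO):** both series upsampled ×2 in time, the
  not-nulled series shifted by TR/2, then the ratio nulled/not-nulled
  removes the shared BOLD component; output is sign-inverted percent change
  so CBV increases are positive.
- **Layer unmixing:** the spatial regression **Y = X·B + U**, with Y the
  n-voxel betas and X the n × 5 layer-weight matrix (WM, deep, middle,
  superficial, CSF); B are least-squares layer responses.
- **Normalized response:** S(s,l,θ) = r(s,l,θ) / r_norm(s) · r̄, with
  r_norm(s) the per-subject RMS over 3 layers × 3 conditions and r̄ its
  group mean; **saliency contrast** SS = S(90°) − S(15°).
- **Behavior:** 3-down-1-up staircases (geometric 15% steps from 0.2863),
  Weibull fit p(C) = γ + (1−γ−λ)(1−e^{−(C/α)^β}), threshold at 80% accuracy,
  sensitivity S = 1/C_threshold, saliency score
  SS_behavior = (S(90°) − S(15°)) / mean(S).
- **Connectivity:** deconvolution-free gPPI — interaction regressor =
  (stimulus boxcar shifted by one TR) ⊙ z-scored seed; saliency-dependent
  connectivity is the 90°−15° interaction-beta difference, feedforward
  (V1 superficial → IPS middle) vs feedback (IPS deep → V1 deep).
- **Retinotopy:** pRF coordinates corrected so the localizer peak maps to
  (127.88°, 4.28°); responses back-projected as unit-volume Gaussians and
  normalized by the across-depth maximum.
- **Inference:** rm-ANOVA with Greenhouse–Geisser correction, paired t,
  Pearson r with max-statistic permutation FWE, Holm adjustment, and 95%
  BCEA = π · χ²₂(0.95) · σx σy √(1−ρ²) for fixation stability.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (seed 1, 20 simulated subjects) and write tidy tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_behavior.R
Rscript analysis/03_laminar.R
Rscript analysis/04_connectivity.R
Rscript analysis/05_fieldmap.R
Rscript analysis/06_stats.R
```

Output of the behavioral and laminar stages:

```
mean sensitivity: S(90) = 20.419, S(15) = 9.734
paired t(19) = 6.829, p = 1.62e-06 (90 vs 15 degrees)
mean behavioral saliency score SS = 0.649

v1   SS by depth: deep 0.325, middle 0.508, superficial 1.062  peak: superficial  F(2,38) = 270.431, p = 3.36e-23
v2   SS by depth: deep 0.369, middle 0.927, superficial 1.053  peak: superficial  F(2,38) = 254.206, p = 1.01e-22
ips  SS by depth: deep 0.403, middle 1.068, superficial 0.516  peak: middle  F(2,38) = 319.744, p = 1.69e-24
```

Sensitivity to the high orientation-contrast foreground is roughly twice
that to the low-contrast one, and the saliency contrast SS peaks in the
superficial layers of the V1-like region but in the middle layers of the
IPS-like region — the laminar signature of a saliency signal computed in V1
and fed forward to parietal cortex. The connectivity stage prints the
matching asymmetry (feedforward delta 0.393, t(19) = 11.763; feedback delta
0.046, n.s.), and the field-map stage reconstructs the saliency signal at
the stimulus location, strongest at the superficial depth.

A quick interactive taste:

```r
library(lamsal)
tl  <- generate_block_design(6, 30, 15, 200, c(200, 300, 400), 60,
                             c(90, 15, 0), seed = 1)
ph  <- generate_laminar_phantom(500, "v1_like", effect_size = 1, seed = 1)
run <- simulate_paired_vaso_run(ph, tl, seed = 1)
fit <- fit_block_glm(boco_correct(run), tl)
unmix_layers(fit$betas[, "theta90"], ph$W)$B
#>          wm        deep      middle superficial         csf
#> -0.10565689  1.29653577  1.67810593  2.43532579 -0.04714873
```

compared with the phantom's generating amplitudes of 0, 1.3, 1.6, 2.4, 0.

Deposited per-participant tables (XLSX workbook or a directory of CSV
sheets; see `?reproduce_deposited` for the sheet schemas) can be re-analyzed
with `reproduce_deposited(path, "behavior")` and friends.

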