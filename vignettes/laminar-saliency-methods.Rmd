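---
title: "Methods: laminar VASO analysis of visual saliency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar VASO analysis of visual saliency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamsal)
```

## What the package models

`lamsal` implements a complete analysis chain for laminar cerebral-blood-volume
(VASO) fMRI studies of visual saliency: where in cortical depth does a
saliency signal — the response advantage for a high orientation-contrast
foreground over a low-contrast one — first arise, and how does it propagate
between V1 and the intraparietal sulcus (IPS)? Because the raw scans of such
a study cannot be regenerated at a desk, the package ships a synthetic-data
module that simulates every input with known ground truth, so every stage of
the chain can be validated by parameter recovery.

The experimental design being emulated: texture stimuli (a small foreground
of bars tilted θ ∈ {90°, 15°, 0°} against a uniform background) shown in
30-s blocks separated by 15-s fixation, six blocks per 270-s run, 60 brief
(200 ms) texture presentations per block with inter-stimulus intervals drawn
from {200, 300, 400} ms. Paired blood-nulled and not-nulled volumes are
acquired alternately with a paired repetition time of 5.02 s.

## Synthetic data: what it emulates and what it does not

**Laminar phantoms.** Each voxel receives a partial-volume weight row over
five compartments (white matter, deep, middle, superficial, CSF) drawn from
a Dirichlet distribution concentrated at the voxel's nominal depth
(`pv_concentration`, default 50 — voxels are mostly but not purely one
compartment, as for ~0.8-mm voxels against a ~2-mm ribbon). Ground-truth
layer amplitudes `B_true` (percent signal change) encode where the 90°-vs-15°
effect peaks: superficial for V1-like profiles, middle for IPS-like. The peak
contrast equals `effect_size` (default 1.0% — the scale of reported laminar
CBV effects), and baseline responses sit near 1%.

**Paired VASO runs.** The neural response per condition is the block boxcar
convolved with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
ratio 1/6, unit peak). The nulled series *decreases* with CBV increase while
both series share a positive BOLD-like component (`bold_gain`, default 0.5
relative to the CBV amplitude; the true residual contamination in nulled
volumes is not known, so it is a parameter, not a constant). Gaussian noise
(`noise_sd`, default 0.5% — mid-range for sub-millimetre 7T protocols) and a
linear drift complete the model. Not emulated: motion, distortion, MR
physics, physiological noise spectra, and draining-vein geometry; passing
tests therefore show estimator correctness under the stated noise model, not
robustness to real-scanner artefacts.

**Event packing.** 60 events of 200 ms with a mean 300-ms interval exactly
fill a 30-s block. Independent interval draws can overflow the block, so the
generator uses a balanced shuffle of the interval menu, rescaled to the
block's interval budget, with the final slot pinned to the block boundary.
This satisfies the schedule's simultaneous constraints (exact event count,
exact block length, events inside their block) while keeping interval order
random.

**Gaze.** A bivariate AR(1) process (lag-1 coefficient 0.95) whose
stationary covariance matches the requested moments, so fixation-stability
estimators face realistic autocorrelation rather than white noise; blinks
are a Poisson process with 100-ms mean duration.

**Observers.** Weibull psychometric functions
p(C) = γ + (1 − γ − λ)(1 − exp(−(C/α)^β)) with guess rate γ = 0.5 (2AFC) and
lapse rate λ = 0.01.

## The analysis chain

**BOLD correction (BOCO).** Both series are temporally upsampled by two
(linear interpolation; Whittaker–Shannon sinc is available but linear is the
default, matching common practice), the not-nulled series is shifted by half
a paired TR onto the nulled grid, and the ratio nulled/not-nulled cancels
the shared BOLD-weighted component. The output is expressed as percent
change about the per-voxel median of the ratio and sign-inverted so CBV
increases are positive.

**Block GLM.** Ordinary least squares per voxel. Condition regressors are
HRF-convolved boxcars scaled to unit plateau (betas read as percent signal
change); nuisance regressors are Legendre polynomials to order 2 plus any
user-supplied columns. One numerical choice matters: for BOCO output the
condition regressors are sampled at the native paired-TR grid and passed
through the same linear upsampling as the data. Building them directly on
the upsampled grid leaves a ~6% amplitude bias, because the interpolated
data cut the corners of the convolved response while an exactly sampled
regressor does not.

**Layer unmixing.** The spatial regression Y = X·B + U, with Y the voxel
betas and X the n × 5 layer-weight matrix, solved by least squares for all
five compartments jointly; the three cortical layers are reported and
WM/CSF retained for quality control. Standard errors come from the residual
variance and (XᵀX)⁻¹. Requires column rank 5 and at least as many voxels as
compartments.

**Normalization.** S(s,l,θ) = r(s,l,θ) / r_norm(s) · r̄, where r_norm(s) is
the per-subject root mean square over the 9 cells (3 cortical layers × 3
conditions) and r̄ its group mean. Whether the normalizer should include
WM/CSF cells is not decidable from the method's description; the 9-cell
domain matches the cells the statistic is computed over, and the package
fixes it there. The per-subject RMS of S then equals r̄ identically — a
tested invariant. Saliency contrasts: SS = S(90°) − S(15°) (insensitive to
background suppression, which affects 90° and 15° alike), the alternative
S(90°) − S(0°), and the suppression contrast (S(90°)+S(15°))/2 − S(0°).

**gPPI without deconvolution.** The seed timeseries is z-scored per run; the
interaction regressor per condition is the elementwise product of the
stimulus boxcar *shifted by one TR* (a coarse haemodynamic delay, avoiding
deconvolution of an uncertain CBV HRF) and the z-scored seed. We read
"product of the stimulus regressor and the seed timecourse" as the
elementwise product: a scalar dot product would not yield a regressor. The
shift defaults to one sample of the analyzed series (2.51 s after
upsampling) and is configurable, since a one-paired-TR reading (5.02 s) is
also defensible. The GLM contains seed, stimulus boxcars, the three
interaction terms and nuisance drift; saliency-dependent connectivity is the
90°-minus-15° interaction beta. Pathways: feedforward = V1 superficial seed
to IPS middle target, feedback = IPS deep to V1 deep, fitted per hemisphere
and averaged. The estimator recovers a generating coupling difference up to
HRF-induced attenuation; the recovery tests measure this rather than assume
it away. BOLD-like series are the default input (higher SNR), with CBV as an
option.

**pRF back-projection.** Polar angle is corrected piecewise-linearly so the
per-hemisphere localizer peak (Am, Em) maps onto the stimulus location
(127.88°, 4.28°) with the vertical meridians pinned; eccentricity scales by
Ec = E/Em · 4.28°. Angles run 0–180° from the upper vertical meridian within
each hemisphere, left hemisphere representing the right hemifield — the
convention under which 127.88° lands in the lower quadrant containing the
stimulus. Each node contributes a unit-volume isotropic Gaussian of its pRF
size at the Cartesian position of (Ac, Ec); maps are response-weighted sums
per depth, all depths divided by the single across-depth maximum (so laminar
differences survive), then averaged over subjects. Grid: x ∈ [−8°, 8°],
y ∈ [−8°, 0°], 0.1° steps — the lower-field extent of the stimulus. One
caveat of unit-volume normalization: point-like foveal pRFs turn background
activity into sharp spikes; the pipeline's synthetic field stage floors the
node size at 0.3° for map building.

**Psychophysics.** The 3-down-1-up staircase uses geometric steps (÷1.15
after three consecutive correct, ×1.15 after an error) — the standard
reading of "changed by 15%" that keeps contrast positive — starting at
0.2863 and clipped at 1. Sessions interleave four 60-trial staircases in
random order. The Weibull is fitted by maximum likelihood on (log α, log β)
from five starting points (local optima are real at these trial counts),
with γ = 0.5 and λ = 0.01 fixed: the procedure description names no free
lapse, and letting λ float is poorly identified from 240 trials. The
threshold is the contrast where the *raw* fitted accuracy is 80% (not
lapse-corrected), and sensitivity is S = 1/C. The staircase itself
equilibrates near 79.4% correct, so the 80% point is an interpolation, not
an extrapolation. The behavioral saliency score is
(S(90°) − S(15°)) / mean(S).

**Group inference.** Repeated-measures ANOVA (one or two within factors)
with Mauchly's test and Greenhouse–Geisser correction, via a multivariate
linear model; paired t tests and Pearson correlations are classical
two-sided tests. Family-wise error across ROIs uses the max-statistic
permutation test: shuffle the behavioral vector, record the maximum absolute
correlation over ROIs, and compare observed |r| against that null
(two-sided, consistent with the package's reporting convention). The add-one
estimator (1 + exceedances)/(n_perm + 1) keeps p > 0; exhaustive enumeration
is available for n ≤ 7 and is exact. Fixation stability is the 95% bivariate
contour ellipse area, BCEA = π · χ²₂(0.95) · σx σy √(1 − ρ²) with
χ²₂(0.95) = 5.9915; the χ² parameterization is the default and the constant
is an argument, since part of the literature parameterizes the ellipse by a
k-factor. Gaze preprocessing: blinks extended ±200 ms, linear interpolation,
linear detrend, per-stimulus-block mean subtraction.

## Problem sizes and runtime choices

The validation suite uses the study's own design scale: 270-s runs, paired
TR 5.02 s (53 pairs, 106 analyzed timepoints), 500-voxel ROIs (the order of
the upsampled per-ROI voxel counts reported for V1), 20 subjects, four
60-trial staircases per condition. Recovery suites run 100–200 seeded
replicates; the permutation-calibration study uses 500 meta-replicates of
1,000 permutations with correlations computed by matrix products. The
pipeline driver caches its bundle so downstream analysis scripts re-read
rather than recompute.

## Known limitations

- The canonical HRF is a stand-in; the acquisition tool's exact block
  impulse shape is not reproduced, and VASO's slower haemodynamics share the
  BOLD HRF here (no onset shift), which block designs largely forgive.
- The synthetic brain–behavior link is a single latent trait scaling both
  the laminar effect and the 90° sensitivity; real inter-subject covariance
  is richer, so pipeline correlations are stronger than empirical ones.
- No spatial structure within compartments: unmixing is exactly correctly
  specified in simulation, which tests the estimator, not model mismatch.
- Bayes factors are out of scope; inference is frequentist throughout.
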