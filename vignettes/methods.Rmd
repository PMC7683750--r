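---
title: "Simulating and evaluating synthetic-CT attenuation correction for pelvic PET/MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating synthetic-CT attenuation correction for pelvic PET/MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

PET attenuation correction (AC) on PET/MRI systems is the weak link of
quantification in the pelvis: the scanner's Dixon-segmentation AC assigns
bone the attenuation of fat, and the missing bone attenuation propagates
into a systematic underestimation of reconstructed activity. `sctpet`
builds a closed, fully synthetic test bed for that problem: it generates
pelvis phantoms with known anatomy, activity and attenuation; computes
three candidate μ-maps (CT-derived reference, Dixon-style emulation,
multi-atlas synthetic CT); simulates attenuated PET acquisition and OSEM
reconstruction under each; and quantifies the resulting errors exactly as a
clinical evaluation would — percentage-error maps against the CT-corrected
reconstruction, regional statistics, VOI SUV errors, and paired
signed-rank tests.

Everything is deterministic given a seed, so every number the package
reports can be recomputed bit-identically.

## The phantom generator

The generator is first-class, tested code, not a fixture. A canonical
pelvis is drawn procedurally on a fixed 400 × 400 × 120 mm field of view
(any grid from 32 × 32 × 8 up renders the same anatomy): elliptical body
with a subcutaneous fat rim, two hip-bone columns and a sacrum — each a
cortical shell around a trabecular core — a bladder, a prostate, and
optional bowel-gas pockets carved into anterior soft tissue.

* **CT model.** Per-label Gaussian HU draws (fat −90 ± 20, soft tissue
  40 ± 15, bladder 10 ± 10, prostate 45 ± 10, trabecular bone 300 ± 80,
  cortical bone 1100 ± 150; air and gas −1000), clipped to [−1000, 2000].
  A global bone-HU scale factor (default 1) emulates lower-density bone in
  older cohorts.
* **MR model.** T2-like per-label means (fluid and fat bright, cortical
  bone dark), a 10 % multiplicative smooth bias field, and Gaussian noise
  with SD 3 % of the soft-tissue mean. This gives registration enough
  structure without simulating MR physics; Dixon echoes and sequence
  physics are out of scope.
* **Deformation.** Inter-individual anatomy is emulated by smooth random
  displacement fields: white noise smoothed with a Gaussian of 30 mm
  correlation length, scaled so the *peak* displacement magnitude equals
  the amplitude parameter (default 6 mm) — "amplitude" in the usual
  physical sense of a field's peak value. Fields whose mapping folds
  (non-positive Jacobian determinant anywhere) are rejected and redrawn.
  The drawn field is returned as ground truth, which is what makes the
  registration-recovery tests possible.
* **Activity.** [¹¹C]acetate-like uptake is specified in SUV units per
  tissue (soft tissue 1.0, fat 0.4, bladder 1.8, trabecular bone 0.8,
  cortical bone 0.3, prostate 2.5) and converted to Bq/ml per subject from
  an injected dose ~N(431, 53²) MBq and weight ~N(79.3, 7²) kg, clipped to
  plausible ranges. No reference prescribes the extra-prostatic
  distribution of this tracer, so the baselines are design constants,
  deliberately flagged as such. A spherical hotspot (radius 9 mm, shrunk
  until it fits) inside the prostate carries `hotspot_contrast` (default 3)
  times the prostate uptake.
* **Bowel gas.** Pockets are drawn independently for the "CT-session"
  anatomy (`ct_true`, `seg_true`) and the "MR-session" anatomy (`mr`,
  activity), emulating air that moves between examinations; the
  preprocessing step that replaces internal air with water exists precisely
  to neutralise this mismatch.

What passing tests on these phantoms shows — and what it does not: the
phantoms exercise bone/fat/soft/air contrast, inter-subject deformation,
session-to-session gas mismatch and realistic HU/μ/SUV scales, so
direction-and-ordering conclusions (which AC method is better, and where)
transfer in kind. They are not patient-realistic: organ shapes are
ellipsoidal, MR texture is minimal, and absolute error magnitudes on real
anatomy will differ.

## Synthetic-CT generation

The generator follows the standard three-step multi-atlas pattern:

1. **Segmentation.** Every template MR is registered to the subject MR
   (below); the fields are applied to the template segmentations, and the
   subject segmentation is a weighted majority vote, ties to the lowest
   label id.
2. **Constrained warping.** Each stage-1 field initialises a second
   registration driven not by intensity but by agreement of the segmented
   structures: demons forces on Gaussian-smoothed (6 mm) per-structure
   indicator maps, with bone compartments merged and soft organs pooled
   (their HU are near-identical, which is all that matters for the CT
   candidates). Smoothed indicators were chosen over signed-distance maps:
   they behave identically near boundaries, are differentiable everywhere,
   and cost one smoothing pass per structure. The refined fields applied to
   the template CTs yield one HU candidate per template.
3. **Fusion.** Per voxel, candidates are combined by the *weighted median*:
   the smallest value whose cumulative weight reaches half the total —
   deterministic, and equal to the lower median under uniform weights.
   Weights are w = exp(−D/σ²) with D the patch-local (radius 2 voxels)
   mean-squared difference between the subject MR and each warped template
   MR; σ² defaults to the mean of D over candidates and voxels, so the
   kernel adapts to the phantom's noise level. The published systems this
   emulates learn their voting and fusion weights from training data; the
   similarity kernel keeps the same promote-what-matches behaviour while
   being fully specified and testable.

Fused output is clipped to [−1000, 2000] HU.

## Registration

The in-package engine composes an affine stage (Nelder–Mead over 12
parameters, translation solved first; metric mean-squared difference on
normalised intensities, with a mutual-information option for
cross-modality use — MI needs lightly smoothed images to give the
histogram a smooth optimum) and a multiresolution demons-type free-form
stage (levels 2×, 1×; 80 and 60 iterations; per-iteration update capped at
3 mm, fluid smoothing 3 voxels, elastic smoothing 0.5 voxels). Two
numerical choices matter:

* **Noise gating.** The demons force is zeroed where the residual is below
  3× the noise spread estimated from the flattest half of the image at
  each level. Without it, homogeneous interiors random-walk under
  noise-driven forces and the recovered field is *worse* than no
  registration at all in those regions.
* **Aperture limits.** With a piecewise-constant MR model, only the
  boundary-normal component of motion is observable at edges; interiors
  are interpolated by the field smoothing. Mean endpoint errors of ~1 mm
  for 6 mm-peak deformations are achievable; demanding much more from this
  image model would be asking the data for information it does not contain.

The synthetic-CT pipeline uses a lighter schedule (50/25 and 25/12
iterations) — quality there is bounded by the atlas, not the optimiser.

## PET simulation and reconstruction

A 2D parallel-beam model per axial slice stands in for the scanner's 3D
time-of-flight geometry: the object of study is the *difference between
AC maps*, not scanner fidelity (TOF would shrink all absolute errors).
The projector is a pixel-driven sparse matrix — each pixel splats linearly
onto the two nearest radial bins, weighted by the pixel pitch — so the
backprojector is its exact transpose and adjointness holds to machine
precision. Line integrals of μ (cm⁻¹ × mm × 0.1) give per-LOR survival
factors; the same factors from any *candidate* μ-map are folded into the
OSEM system model, so an erroneous candidate produces exactly the
quantification bias a scanner would show. Subsets partition angles by
stride and are visited in golden-ratio order, which markedly accelerates
early convergence; defaults are the clinical 2 iterations × 28 subsets
with 112 angles (so 28 divides them). The self-consistency check (true-μ
AC, noise-free, 10 iterations) uses a 96² grid with 168 single-angle
subsets — at that setting the body-voxel MAE converges below 3 % of the
body mean; no scatter, randoms or resolution modelling is included, by
design.

## Pre-processing rules

Before comparison, volumes are harmonised the way a clinical CT-vs-sCT
study must be: internal air below −400 HU becomes water (0 HU); the CT and
sCT outer contours are forced to the Dixon-derived contour (outside →
−1000 HU, air-like inside → 0 HU; the −400 HU air test is also used to
detect where tissue must be added, since no finer rule is available);
missing inferior CT slices are emulated by cropping and re-padding with
the nearest slice, and the padded slices are carried as an explicit
validity mask and excluded from all statistics and VOIs rather than
cropped, so geometry never changes. Contour harmonisation is idempotent.

## Evaluation

Percentage-difference maps use the CT-corrected image as reference and are
restricted to body voxels on valid slices whose reference value exceeds
5 % of the body mean — the reference floor is the package's choice of
denominator guard; without it near-zero-uptake voxels dominate the
histograms. Statistics (mean, SD, MAE, RMSE) are computed per subject
(bone defined per subject as reference μ > 0.102 cm⁻¹, strictly) and
summarised across the cohort as the unweighted mean of per-subject values;
a voxel-pooled mode is provided since pooling conventions differ between
studies. SD is the population SD, so RMSE² = mean² + SD² holds exactly and
is asserted in the tests. Common-space mean maps register every subject MR
to the subject whose body volume sits at the cohort median and average
wherever at least half the cohort contributes. The Wilcoxon signed-rank
test drops zero differences, uses mid-ranks for ties, and enumerates all
2ⁿ sign assignments for n ≤ 15 (exact even under ties; the evaluated
cohorts have n = 12 or fewer), switching to a tie- and
continuity-corrected normal approximation above.

## Problem sizes

The shipped study configuration — also what `scripts/acceptance.R` runs —
uses 10 held-out subjects, 5 templates and 64 × 64 × 12 grids
(6.25 × 6.25 × 10 mm voxels), noise-free projection, and the clinical OSEM
protocol. These sizes give stable cohort orderings (the Dixon-vs-sCT
contrasts are an order of magnitude larger than their spread) while a full
run completes in minutes on one CPU; grids up to 128 × 128 × 32 and
cohorts of 15 templates / 12 subjects run unchanged, just longer.

## Known limitations

* Phantom anatomy is ellipsoid-based; no implants, no lungs, no
  truncation (phantoms always fit the FOV, so truncation completion is
  unnecessary).
* The MR model's flat-with-noise tissue interiors bound what deformable
  registration can recover (see aperture note above).
* Non-TOF 2D reconstruction exaggerates absolute attenuation-error effects
  relative to a TOF scanner.
* The Dixon emulator uses the ground-truth segmentation, so its only error
  mode is the bone→fat misclassification (plus gas mismatch) — exactly the
  failure mode under study, but narrower than a real fat/water
  decomposition's.
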