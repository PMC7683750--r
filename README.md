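# sctpet

Simulation framework for evaluating MRI-derived synthetic-CT attenuation
correction of pelvic PET against CT-based and Dixon-segmentation-based
correction.

## The problem

PET quantification requires a map of 511-keV linear attenuation coefficients
(μ, cm⁻¹). On PET/MRI systems no CT is available: the scanner's standard
approach segments a Dixon fat/water MR acquisition into air, fat and soft
tissue and assigns populational μ values — and, critically, assigns **bone**
the attenuation of fat. The missing bone attenuation biases reconstructed
activity downward, inside and near bone especially, which matters for
prostate imaging where the target sits between the hip bones and sacrum.

Multi-atlas synthetic-CT (sCT) methods estimate a patient-specific CT-number
volume from a diagnostic T2-weighted MR image instead. This package
implements, end to end and on fully synthetic pelvis phantoms:

* a **phantom generator** — a procedural pelvis (body, subcutaneous fat rim,
  hip bones and sacrum with cortical shell and trabecular core, bladder,
  prostate, movable bowel-gas pockets) rendered as paired MR-like and
  CT-like volumes with tissue labels, deformed by smooth random displacement
  fields to create template databases and held-out subject cohorts, with
  [¹¹C]acetate-like activity maps, a prostate VOI and an intra-prostatic
  hotspot;
* a **multi-atlas sCT generator**: deformable registration of every template
  MR to the subject MR (affine + multiresolution demons), weighted-vote
  segmentation, label-driven constrained warping of the template CTs, and
  voxelwise **weighted-median fusion** with patch-similarity weights
  w = exp(−D/σ²), D the local mean-squared MR difference;
* **attenuation-map construction**: the bilinear conversion
  μ(HU) = μ_w·(HU+1000)/1000 for HU ≤ 0 and μ_w + k·HU above (defaults
  μ_w = 0.096 cm⁻¹, k = 4·10⁻⁵ cm⁻¹/HU), and a Dixon-style emulator that
  maps bone to fat μ;
* a **PET simulator**: 2D parallel-beam attenuated forward projection per
  slice (sparse system matrix, exactly adjoint backprojector), optional
  Poisson noise, and OSEM reconstruction (default 2 iterations, 28 subsets)
  with any candidate μ-map folded into the system model;
* the **error analysis**: voxelwise percentage-difference maps against the
  CT-corrected reference, mean/SD/MAE/RMSE per region (whole body, bone,
  soft tissue; bone = reference μ > 0.102 cm⁻¹, per subject), common-space
  cohort mean error maps, VOI SUV errors (%ΔSUV), histograms, and exact
  paired Wilcoxon signed-rank tests.

## Worked example

```r
library(sctpet)

cfg <- pipeline_config(seed = 4, n_templates = 3, n_subjects = 2,
                       grid_shape = c(64, 64, 12), n_missing_slices = 2)
res <- run_pipeline(cfg, "demo_run", quiet = TRUE)
subset(res$cohort, modality == "pet",
       select = c(method, region, mean, sd, mae, rmse))
```

```
 method region        mean        sd       mae      rmse
  dixon  whole -15.2492382 29.149137 17.863892 32.898294
  dixon   bone -77.5706769 14.664591 77.570677 78.945737
  dixon   soft  -4.2652966 12.481988  7.341431 13.198550
    sda  whole  -0.4435479  5.368513  3.141992  5.405985
    sda   bone  -1.9894540  9.834669  7.706954 10.041949
    sda   soft  -0.1708582  4.043561  2.336994  4.073796
```

Read: with the scanner-style Dixon correction the reconstructed PET activity
in bone voxels is grossly underestimated on these phantoms (bone is treated
as fat, and bone uptake is low, which inflates percentage errors); with the
synthetic-CT correction the mean bone error shrinks to about −2 %, and
whole-volume and soft-tissue errors drop accordingly. `res$voi` holds
per-subject prostate and hotspot %ΔSUV values and `res$tests` the paired
Wilcoxon comparisons between the two methods. Every run writes
`per_subject_stats.csv`, `cohort_stats.csv`, `voi_results.csv`,
`summary.json` and its resolved `config.yaml` into the output directory;
reruns with the same configuration are bit-identical and reuse cached
stages.

A thin CLI over the same functions lives at `inst/cli/sctpet.R`
(`generate`, `sct`, `run` subcommands).

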