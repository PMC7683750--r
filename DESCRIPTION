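Package: sctpet
Title: Synthetic-CT Attenuation Correction Evaluation for Pelvic PET/MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation pipeline for evaluating MRI-derived synthetic-CT
    attenuation correction of pelvic PET against CT-based and Dixon-segmentation-based
    attenuation correction. Provides procedural pelvis phantoms with paired MR-like and
    CT-like volumes, a multi-atlas synthetic-CT generator (deformable registration,
    weighted-vote segmentation, constrained warping, weighted-median fusion), bilinear
    HU-to-mu conversion at 511 keV, a Dixon-style segmentation attenuation-map emulator,
    parallel-beam forward projection with attenuation and ordered-subset
    expectation-maximization (OSEM) reconstruction, and the quantitative error analysis:
    regional percentage-error statistics, common-space mean error maps, VOI SUV errors,
    and exact Wilcoxon signed-rank testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
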