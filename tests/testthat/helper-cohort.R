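## The cohort study used by the direction-and-ordering checks: 10 held-out
## subjects, 5 templates, 64 x 64 x 12 grids, noise-free reconstruction.
## Memoised because it is the most expensive fixture of the suite.

cohort_study_config <- function(seed = 20) {
  pipeline_config(seed = seed, n_templates = 5, n_subjects = 10,
                  grid_shape = c(64, 64, 12), n_angles = 112,
                  n_iterations = 2, n_subsets = 28, noise_scale = NULL,
                  n_missing_slices = 2, common_space = FALSE)
}

fx_cohort_study <- function() get_fixture("cohort_study", function() {
  dir <- file.path(tempdir(), "sctpet_cohort_study")
  unlink(dir, recursive = TRUE)
  run_pipeline(cohort_study_config(), dir, quiet = TRUE)
})
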