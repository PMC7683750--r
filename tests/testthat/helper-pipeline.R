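## Tiny end-to-end pipeline runs shared between the I/O tests (smoke, cache
## consistency) and the determinism acceptance check. Memoised: the two
## reference runs execute once per test session.

tiny_pipeline_config <- function() {
  pipeline_config(seed = 3, n_templates = 2, n_subjects = 2,
                  grid_shape = c(48, 48, 8), n_angles = 56, n_subsets = 28,
                  n_missing_slices = 1, common_space = TRUE)
}

fx_pipeline_runs <- function() get_fixture("pipeline_runs", function() {
  cfg <- tiny_pipeline_config()
  dir_a <- file.path(tempdir(), "sctpet_run_a")
  dir_b <- file.path(tempdir(), "sctpet_run_b")
  unlink(c(dir_a, dir_b), recursive = TRUE)
  res_a <- run_pipeline(cfg, dir_a, quiet = TRUE)
  res_b <- run_pipeline(cfg, dir_b, quiet = TRUE)
  list(cfg = cfg, dir_a = dir_a, dir_b = dir_b, res_a = res_a, res_b = res_b)
})
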