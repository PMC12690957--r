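# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# a small, fast simulation for structural unit tests
smallSim <- function() {
  if (is.null(.fixture_env$small))
    .fixture_env$small <- simulateShadeExperiment(
      shadeSimConfig(n_genes = 120, n_regions = 140, n_tf_peaks = 40,
                     chrom_length = 9e5, n_blacklist_promoter = 2L,
                     n_blacklist_distal = 1L),
      seed = 7)
  .fixture_env$small
}

# the full default pipeline run used by recovery and acceptance tests
defaultRun <- function() {
  if (is.null(.fixture_env$run)) {
    dir <- file.path(tempdir(), "chromShade_default_run")
    .fixture_env$run <- suppressMessages(
      runShadePipeline(shadePipelineConfig(), out_dir = dir, seed = 1))
    .fixture_env$run_dir <- dir
  }
  .fixture_env$run
}

defaultRunDir <- function() {
  defaultRun()
  .fixture_env$run_dir
}
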