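## Session-cached fixtures shared across test files. The default-condition
## pipeline run is the expensive fixture (a few minutes); it is computed at
## most once per test session.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 5) {
  cfg <- cachescan::default_config(seed)
  cfg$simulate$n_proteins <- 120L
  cfg$simulate$n_members <- 12L
  cfg$profiles$calibration_n <- 250L
  cfg
}

default_run_fixture <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- cachescan::run_pipeline(
      cachescan::default_config(1),
      out_dir = file.path(tempdir(), "cachescan-default-run"),
      force = TRUE)
  }
  .fixture_env$run
}

detection_fixture <- function() {
  if (is.null(.fixture_env$detect)) {
    run <- default_run_fixture()
    .fixture_env$detect <- cachescan::detection_benchmark(run$proteome,
                                                          rng_seed = 2)
  }
  .fixture_env$detect
}
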