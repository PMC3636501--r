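# Shared desk-preset experiment for the replication tests: run once per
# test session, cached across test files.
desk_cache <- new.env(parent = emptyenv())

desk_result <- function() {
  if (is.null(desk_cache$res)) {
    desk_cache$res <- suppressWarnings(
      run_experiment(experiment_config("desk", seed = 1), verbose = FALSE))
  }
  desk_cache$res
}
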