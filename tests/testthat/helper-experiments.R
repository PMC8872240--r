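# Full-scale preset experiments are expensive; several acceptance checks look
# at different aspects of the same runs, so results are memoised per
# (preset, seed) for the duration of the test session.

.experiment_cache <- new.env(parent = emptyenv())

cached_experiment <- function(preset, seed) {
  key <- paste0(preset, "#", seed)
  if (is.null(.experiment_cache[[key]])) {
    .experiment_cache[[key]] <- run_experiment(preset_config(preset, seed = seed))
  }
  .experiment_cache[[key]]
}
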