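# The default 64 x 64 phantom is used by several integration tests; simulate
# each repeat count once per test run.
.phantom_cache <- new.env(parent = emptyenv())

default_sim_cached <- function(N = 4L, seed = 1L) {
  key <- sprintf("s%d_n%d", seed, N)
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- simulate_volume(
      default_phantom_config(seed = seed, N = N))
  }
  .phantom_cache[[key]]
}
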