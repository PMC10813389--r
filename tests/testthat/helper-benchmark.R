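# The scaled-down benchmark is expensive (~10 min); run it once per test
# session, lazily, and share the result across acceptance tests.
.benchmark_cache <- new.env(parent = emptyenv())

get_acceptance_benchmark <- function() {
  if (is.null(.benchmark_cache$res)) {
    message("running the scaled-down acceptance benchmark (several minutes)")
    .benchmark_cache$res <- run_benchmark(seed = 1L, verbose = TRUE)
  }
  .benchmark_cache$res
}
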