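# the default 50-seed benchmark is shared by the saturation and
# precision-improvement checks; compute it once per test run
.benchmark_cache <- new.env(parent = emptyenv())

default_benchmark <- function() {
  if (is.null(.benchmark_cache$sat)) {
    .benchmark_cache$sat <- haracne::saturation_experiment(
      n_seeds = 50, seed = 1
    )
  }
  .benchmark_cache$sat
}
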