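# One shared scaled-down replicate run of the simulation-evaluation grid
# (additive model, genotype relative risks 1.2 and 2.0), computed lazily
# and reused by every test that needs replicate-level metrics.

.run_cache <- new.env(parent = emptyenv())

shared_experiment <- function(reps = 100L, seed = 424242L) {
  key <- paste0("exp_", reps, "_", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- suppressWarnings(
      run_experiment(modes = "additive", grrs = c(1.2, 2.0), reps = reps,
                     n_families = 200L, seed = seed))
  }
  .run_cache[[key]]
}
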