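# shared fixtures, built once per test run

.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(cohort_config(seed = seed))
  .cohort_cache[[key]]
}

# small, fast cohort for pipeline-level tests
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_config(n_trees = 3L, n_samples = 40L,
                                seed = seed, ...))
}

# clean band-model spectrum without touching the RNG
clean_spectrum <- function(target = 3.2, ring = 15,
                           cfg = cohort_config()) {
  tracheidnir:::spectrum_clean(target, ring, cfg)
}
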