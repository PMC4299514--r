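# Shared, lazily computed cohort analysis used by the acceptance tests:
# a 20-line synthetic cancer cohort at default noise, tailored and sampled
# once per session.

.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (!exists("result", .cohort_cache)) {
    tc <- build_toy_core(check = FALSE)
    cohort <- generate_cohort(tc, n_lines = 20, seed = 7)
    res <- cohort_warburg(tc, cohort$expression, n_samples = 1000, seed = 7)
    .cohort_cache$result <- list(model = tc, cohort = cohort, warburg = res)
  }
  .cohort_cache$result
}
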