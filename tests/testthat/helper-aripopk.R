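# Shared fixtures: final published parameter set and small cohorts.

table3 <- final_model_params()

small_cohort <- function(n = 20, seed = 1, pop = table3, ...) {
  generate_cohort(cohort_spec(n_subjects = n, ...), pop, seed = seed)
}

# Independent brute-force superposition oracle: loop over doses, no shared
# code with the package's vectorized implementation.
brute_conc <- function(cl, v, ka, dose_mg, dose_times, t) {
  ke <- cl / v
  total <- 0
  for (td in dose_times) {
    if (td > t) next
    dt <- t - td
    total <- total + (dose_mg / v * 1000) * ka / (ka - ke) *
      (exp(-ke * dt) - exp(-ka * dt))
  }
  total
}
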