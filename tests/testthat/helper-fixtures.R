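# shared fixture builders (everything generated in code at test time)

# full preprocessing + selection + APMC chain on a generated cohort; mirrors
# the pipeline stages but keeps every intermediate accessible to assertions
fixture_chain <- function(cohort, dataset = cohort$dataset, k = NULL,
                          n_features = 12, seed = 11) {
  rd <- reduce_dataset(dataset, n_features = n_features)
  run_apmc(rd$dataset, apmc_config(k = k, seed = seed))
}

# tiny complete-data cohort for fast structural tests
small_cohort <- function(n = 120, seed = 1, ...) {
  generate_cohort(synthetic_config(
    n_subjects = n, n_imaging_features = 30, n_informative_features = 6,
    frac_both = 1, frac_imaging_only = 0, frac_genomic_only = 0,
    seed = seed, ...))
}
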