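# Scaled-down simulation studies shared by the acceptance tests.
# Computed once per test run and memoised; every study uses the same
# fixed seed chosen up front.

.study_cache <- new.env(parent = emptyenv())

scaled_design <- function(intervals, n_datasets = 10) {
  simulation_design(n = 250, p = 100, n_true_pos = 5, n_true_neg = 5,
                    effect = log(2), censor_rate = 0.2676,
                    intervals = intervals, block_size = 10, rho = 0.5,
                    n_datasets = n_datasets)
}

scaled_schedule <- function() mcmc_schedule(500, 500, 3, 3, 999)

cached_study <- function(key, maker) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- maker()
  .study_cache[[key]]
}

balanced_study <- function() {
  cached_study("balanced", function() {
    run_simulation_study(scaled_design("balanced"),
                         fcr_model_spec(s = 0.01), scaled_schedule(),
                         methods = c("CI", "BF_gamma", "PrGamma"),
                         seed = 1L)
  })
}

unbalanced_study <- function() {
  cached_study("unbalanced", function() {
    run_simulation_study(scaled_design("fixed"),
                         fcr_model_spec(s = 0.01), scaled_schedule(),
                         methods = c("CI", "BF_gamma", "PrGamma"),
                         seed = 1L)
  })
}

sweep_study <- function() {
  cached_study("sweep", function() {
    run_simulation_study(scaled_design("balanced", n_datasets = 3),
                         fcr_model_spec(), scaled_schedule(),
                         methods = c("BF_gamma", "BF_betagamma", "PrGamma"),
                         s_values = c(0.01, 0.1, 0.5), seed = 1L)
  })
}

study_metric <- function(study, meth, s, col) {
  row <- study$summary[study$summary$method == meth & study$summary$s == s, ]
  row[[col]]
}
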