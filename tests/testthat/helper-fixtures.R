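# Shared expensive fixtures, computed once per test session.
#
# The recovery/model-comparison checks run on the generator's default study
# conditions (n = 723, 67% pragmatic responders, generating bias 2.26) with a
# shortened but well-mixing MCMC schedule (componentwise sweeps; 1,000 kept
# draws over 4 chains, 400 burn-in sweeps, thinning 3).

.fixture_env <- new.env(parent = emptyenv())

fixture_mcmc_config <- function(seed = 11L) {
  mcmc_config(n_samples = 1000L, n_chains = 4L, burn_in = 400L, thin = 3L,
              seed = seed)
}

default_dataset <- function() {
  if (is.null(.fixture_env$dataset))
    .fixture_env$dataset <- generate_dataset(generator_config())
  .fixture_env$dataset
}

recovery_posterior <- function() {
  if (is.null(.fixture_env$recovery))
    .fixture_env$recovery <- run_mcmc(default_dataset(), "rsa_speaker",
                                      fixture_mcmc_config())
  .fixture_env$recovery
}

recovery_map <- function() {
  if (is.null(.fixture_env$recovery_map))
    .fixture_env$recovery_map <- map_estimate(default_dataset(),
                                              "rsa_speaker",
                                              n_starts = 8L, seed = 1L)
  .fixture_env$recovery_map
}

default_comparison <- function() {
  if (is.null(.fixture_env$comparison))
    .fixture_env$comparison <- compare_models(default_dataset(),
                                              config = fixture_mcmc_config())
  .fixture_env$comparison
}
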