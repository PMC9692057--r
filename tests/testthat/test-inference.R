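# Sampler, optimizer, and information criteria, checked against closed-form
# conjugate posteriors and exact leave-one-out refits.

small_dataset <- function(n = 60, seed = 13) {
  generate_dataset(generator_config(n_participants = n, p_pragmatic = 1,
                                    seed = seed))
}

test_that("the Metropolis sampler recovers a conjugate normal posterior", {
  target <- function(par) dnorm(par[1], 1.3, 0.7, log = TRUE)
  cfg <- mcmc_config(n_samples = 4000, n_chains = 4, burn_in = 300, thin = 2,
                     seed = 5)
  res <- stickcontest:::.metropolis(target, lower = -10, upper = 10, cfg)
  expect_equal(mean(res$draws), 1.3, tolerance = 0.1)
  expect_equal(sd(res$draws), 0.7, tolerance = 0.1)
  # identical seeds give identical chains
  res2 <- stickcontest:::.metropolis(target, lower = -10, upper = 10, cfg)
  expect_identical(res$draws, res2$draws)
  # a flat target (prior-only run) explores the box uniformly
  flat <- stickcontest:::.metropolis(function(par) 0, lower = 0, upper = 1,
                                     mcmc_config(n_samples = 4000,
                                                 n_chains = 4, burn_in = 200,
                                                 thin = 2, seed = 8))
  expect_equal(mean(flat$draws), 0.5, tolerance = 0.05)
  expect_gt(min(flat$draws), 0); expect_lt(max(flat$draws), 1)
})

test_that("posterior draws are reproducible and carry pointwise likelihoods", {
  d <- small_dataset()
  cfg <- mcmc_config(n_samples = 100, n_chains = 2, burn_in = 100, thin = 1,
                     seed = 3)
  p1 <- suppressWarnings(run_mcmc(d, "rsa_hom", cfg))
  p2 <- suppressWarnings(run_mcmc(d, "rsa_hom", cfg))
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$pointwise_loglik, p2$pointwise_loglik)
  expect_equal(dim(p1$pointwise_loglik), c(nrow(p1$draws), nrow(d)))
  expect_equal(length(unique(p1$chain_ids)), 2L)
  # pointwise rows match the likelihood recomputed at each kept draw
  i <- 17L
  ll <- dataset_loglik(d, "rsa_hom", as.list(p1$draws[i, ]))
  expect_equal(p1$pointwise_loglik[i, ], ll$pointwise, tolerance = 1e-12)
})

test_that("MAP estimation is seeded, convergent, and beats the truth's fit", {
  d <- generate_dataset(generator_config(n_participants = 700,
                                         p_pragmatic = 1, beta_true = 2,
                                         seed = 17))
  m1 <- map_estimate(d, "rsa_hom", seed = 2)
  m2 <- map_estimate(d, "rsa_hom", seed = 2)
  expect_identical(m1$par, m2$par)
  expect_equal(m1$convergence, 0L)
  # parameter recovery at n = 700
  expect_equal(unname(m1$par[["beta"]]), 2, tolerance = 0.5)
  truth <- dataset_loglik(d, "rsa_hom",
                          list(beta = 2, offset = 0, noise_sd = 0.18))
  expect_gte(m1$loglik, truth$total)
  # with flat priors the ML and MAP optima essentially coincide
  ml <- map_estimate(d, "rsa_hom", use_prior = FALSE, seed = 2)
  expect_equal(unname(ml$par[["beta"]]), unname(m1$par[["beta"]]),
               tolerance = 0.05)
})

test_that("WAIC reduces to -2 lppd for constant draws and is additive", {
  ll_row <- dnorm(c(0.1, -0.4, 0.7), 0, 1, log = TRUE)
  const <- matrix(rep(ll_row, each = 50), nrow = 50)
  w <- waic(const)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll_row))
  expect_equal(w$se, 2 * sqrt(3 * var(ll_row)))
  # duplicating every observation doubles the criterion
  w2 <- waic(cbind(const, const))
  expect_equal(w2$waic, 2 * w$waic)
  l <- psis_loo(const)
  expect_equal(l$psis_loo, w$waic)   # degenerate weights: identical value
})

test_that("WAIC and PSIS-LOO track exact leave-one-out for a conjugate model", {
  set.seed(31)
  n <- 25; tau2 <- 100; sigma <- 1
  y <- rnorm(n, 0.6, sigma)
  v <- 1 / (n / sigma^2 + 1 / tau2); m <- v * sum(y) / sigma^2
  theta <- rnorm(4000, m, sqrt(v))              # exact posterior draws
  ll <- vapply(y, function(yi) dnorm(yi, theta, sigma, log = TRUE),
               numeric(4000))
  # exact LOO refits: each held-out point's posterior-predictive density
  elpd_exact <- vapply(seq_len(n), function(i) {
    vi <- 1 / ((n - 1) / sigma^2 + 1 / tau2)
    mi <- vi * sum(y[-i]) / sigma^2
    dnorm(y[i], mi, sqrt(vi + sigma^2), log = TRUE)
  }, numeric(1))
  loo_exact <- -2 * sum(elpd_exact)
  w <- waic(ll)
  l <- psis_loo(ll)
  expect_equal(w$waic, loo_exact, tolerance = 0.02)
  expect_lt(abs(l$psis_loo - loo_exact), 2 * l$se)
  expect_true(all(is.finite(l$pareto_k) | is.nan(l$pareto_k)))
  expect_true(all(l$pareto_k < 0.7, na.rm = TRUE))
  expect_gte(w$se, 0); expect_gte(l$se, 0)
})

test_that("k-fold cross-validation partitions, fits, and averages", {
  d <- small_dataset(n = 24, seed = 19)
  cv <- kfold_cv(d, "aa_hom", k = 4, seed = 2)
  expect_equal(nrow(cv$fits), 4L)
  expect_named(cv$mean, c("offset", "noise_sd"))
  # k = n gives the leave-one-out partition
  cv_loo <- kfold_cv(d[1:12, ], "aa_hom", k = 12, seed = 2)
  expect_equal(nrow(cv_loo$fits), 12L)
  expect_error(kfold_cv(d[1:3, ], "rsa_speaker", k = 3), "smaller")
})

test_that("heterogeneous variants fit at least as well as their components", {
  d <- default_dataset()
  ml_hom <- map_estimate(d, "rsa_hom", use_prior = FALSE, seed = 1)
  ml_het <- map_estimate(d, "rsa_het", use_prior = FALSE, seed = 1)
  expect_gte(ml_het$loglik, ml_hom$loglik - 1e-3)
})
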