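# Bayesian fitting and model comparison: adaptive random-walk Metropolis over
# each variant's parameter box, multi-start MAP/ML optimization, WAIC,
# PSIS-LOO (with generalized-Pareto tail smoothing), and k-fold CV.

#' MCMC configuration
#'
#' The defaults mirror the analysis configuration: 1,000 kept draws pooled
#' across 4 chains, a burn-in of 7,500 steps and a thinning lag of 100 steps.
#' Proposal scales adapt toward a 0.2-0.5 acceptance rate during burn-in only.
#'
#' @param n_samples Total kept draws pooled across chains.
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param burn_in Discarded adaptation steps per chain.
#' @param thin Keep every `thin`-th post-burn-in step.
#' @param seed Integer seed; the run is reproducible from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 1000L, n_chains = 4L, burn_in = 7500L,
                        thin = 100L, seed = 1L) {
  stopifnot(n_samples >= 2L, n_chains >= 1L, burn_in >= 0L, thin >= 1L)
  structure(list(n_samples = as.integer(n_samples),
                 n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_config")
}

# Componentwise adaptive random-walk Metropolis on a box: each step sweeps
# the coordinates one at a time with per-coordinate Gaussian proposals whose
# scales adapt (toward ~0.44 acceptance) during burn-in only. log_post(par)
# returns the unnormalized log posterior; extras(par) is an optional function
# whose value is stored for each kept draw (the pointwise log-likelihoods).
.metropolis <- function(log_post, lower, upper, config, extras = NULL,
                        init = NULL) {
  np <- length(lower)
  n_keep <- ceiling(config$n_samples / config$n_chains)
  draws <- vector("list", config$n_chains)
  extra_rows <- vector("list", config$n_chains)
  accept <- numeric(config$n_chains)
  set.seed(config$seed)
  for (ch in seq_len(config$n_chains)) {
    par <- if (is.null(init)) lower + stats::runif(np) * (upper - lower)
           else pmin(pmax(init, lower), upper)
    lp <- log_post(par)
    tries <- 0L
    while (!is.finite(lp) && tries < 100L) {
      par <- lower + stats::runif(np) * (upper - lower)
      lp <- log_post(par)
      tries <- tries + 1L
    }
    if (!is.finite(lp))
      stop("non-finite log posterior at initialization", call. = FALSE)
    scale <- (upper - lower) / 10
    n_steps <- config$burn_in + config$thin * n_keep
    kept <- matrix(NA_real_, n_keep, np)
    kept_extra <- vector("list", n_keep)
    n_prop <- 0L; n_acc <- 0L
    acc_win <- integer(np); k <- 0L
    for (step in seq_len(n_steps)) {
      for (j in seq_len(np)) {
        prop <- par
        prop[j] <- par[j] + stats::rnorm(1L, 0, scale[j])
        n_prop <- n_prop + 1L
        if (prop[j] < lower[j] || prop[j] > upper[j]) next
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(stats::runif(1L)) < lp_prop - lp) {
          par <- prop; lp <- lp_prop
          n_acc <- n_acc + 1L; acc_win[j] <- acc_win[j] + 1L
        }
      }
      if (step <= config$burn_in && step %% 25L == 0L) {
        scale <- scale * exp(acc_win / 25 - 0.44)
        acc_win <- integer(np)
      }
      if (step > config$burn_in &&
          (step - config$burn_in) %% config$thin == 0L) {
        k <- k + 1L
        kept[k, ] <- par
        if (!is.null(extras)) kept_extra[[k]] <- extras(par)
      }
    }
    draws[[ch]] <- kept
    extra_rows[[ch]] <- kept_extra
    accept[ch] <- n_acc / n_prop
  }
  list(draws = do.call(rbind, draws),
       chain_ids = rep(seq_len(config$n_chains), each = n_keep),
       extras = do.call(c, extra_rows),
       accept_rate = accept)
}

# split-Rhat per parameter column
.split_rhat <- function(draws, chain_ids) {
  vapply(seq_len(ncol(draws)), function(j) {
    halves <- lapply(split(draws[, j], chain_ids), function(x) {
      h <- length(x) %/% 2L
      if (h < 2L) return(list(x))
      list(x[seq_len(h)], x[(h + 1L):(2L * h)])
    })
    xs <- unlist(halves, recursive = FALSE)
    m <- length(xs); n <- length(xs[[1L]])
    mns <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, stats::var, numeric(1))
    b <- n * stats::var(mns)
    w <- mean(vars)
    if (w == 0) return(1)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1))
}

#' Sample the posterior of a model variant by MCMC
#'
#' Adaptive random-walk Metropolis within each chain over the variant's
#' parameter box (priors as in [variant_parameters()]). Pointwise
#' log-likelihoods are recorded for every kept draw, feeding [waic()] and
#' [psis_loo()]. Chains with split R-hat above 1.1 are reported with a
#' warning, not an error.
#'
#' @inheritParams dataset_loglik
#' @param config An [mcmc_config()].
#' @return An object of class `posterior_draws`: list with `draws` (draw x
#'   parameter matrix), `pointwise_loglik` (draw x participant matrix),
#'   `chain_ids`, `accept_rate`, `rhat`, `variant`, and `config`.
#' @export
run_mcmc <- function(records, variant, config = mcmc_config(),
                     lengths = 1:9) {
  variant <- .check_variant(variant)
  records <- validate_participants(records)
  vp <- variant_parameters(variant)
  ll_fun <- make_loglik(records, variant, lengths)
  log_post <- function(par) {
    names(par) <- vp$names
    lp <- vp$log_prior(par)
    if (!is.finite(lp)) return(-Inf)
    lp + sum(ll_fun(par))
  }
  pointwise <- function(par) {
    names(par) <- vp$names
    ll_fun(par)
  }
  res <- .metropolis(log_post, vp$lower, vp$upper, config,
                     extras = pointwise)
  colnames(res$draws) <- vp$names
  rhat <- .split_rhat(res$draws, res$chain_ids)
  names(rhat) <- vp$names
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("split R-hat > 1.1 for: ",
            paste(vp$names[rhat > 1.1], collapse = ", "),
            " (consider longer chains)", call. = FALSE)
  structure(list(draws = res$draws,
                 pointwise_loglik = do.call(rbind, res$extras),
                 chain_ids = res$chain_ids,
                 accept_rate = res$accept_rate,
                 rhat = rhat, variant = variant, config = config),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior draws: variant '%s', %d draws x %d parameters (%d chains)\n",
              x$variant, nrow(x$draws), ncol(x$draws),
              length(unique(x$chain_ids))))
  qs <- t(apply(x$draws, 2L, stats::quantile, c(0.025, 0.5, 0.975)))
  print(round(cbind(mean = colMeans(x$draws), qs, rhat = x$rhat), 3))
  invisible(x)
}

#' Posterior summary of a fitted variant
#'
#' @param object A `posterior_draws` object.
#' @param prob Central interval probability (default 0.95).
#' @param ... Unused.
#' @return Data frame with posterior mean, median, central interval, and
#'   split R-hat per parameter.
#' @export
summary.posterior_draws <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  qs <- t(apply(object$draws, 2L, stats::quantile, c(a, 0.5, 1 - a)))
  data.frame(parameter = colnames(object$draws),
             mean = colMeans(object$draws),
             lower = qs[, 1L], median = qs[, 2L], upper = qs[, 3L],
             rhat = object$rhat, row.names = NULL)
}

#' Maximum a posteriori (or maximum likelihood) estimate
#'
#' Multi-start box-constrained optimization (L-BFGS-B) of the log posterior,
#' or of the bare log-likelihood with `use_prior = FALSE` (with the uniform
#' priors of [variant_parameters()] the two coincide in the interior).
#' Deterministic given the seed.
#'
#' @inheritParams run_mcmc
#' @param n_starts Number of seeded random starts.
#' @param use_prior Include the log prior (MAP) or not (ML).
#' @param seed Seed for the random starts.
#' @return List with `par` (named vector), `loglik`, `log_posterior`, and
#'   `convergence` (0 = converged for the best start).
#' @export
map_estimate <- function(records, variant, n_starts = 5L, use_prior = TRUE,
                         seed = 1L, lengths = 1:9) {
  variant <- .check_variant(variant)
  records <- validate_participants(records)
  vp <- variant_parameters(variant)
  ll_fun <- make_loglik(records, variant, lengths)
  objective <- function(par) {
    names(par) <- vp$names
    lp <- if (use_prior) vp$log_prior(par) else 0
    val <- lp + sum(ll_fun(par))
    if (!is.finite(val)) 1e10 else -val
  }
  eps <- 1e-6 * (vp$upper - vp$lower)
  lo <- vp$lower + eps; hi <- vp$upper - eps
  set.seed(seed)
  starts <- rbind((lo + hi) / 2,
                  matrix(stats::runif((n_starts - 1L) * length(lo), lo, hi),
                         ncol = length(lo), byrow = TRUE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = lo, upper = hi, control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("optimization failed for all starts", call. = FALSE)
  if (best$convergence != 0L)
    warning("optimizer did not report convergence (code ", best$convergence,
            ")", call. = FALSE)
  par <- best$par
  names(par) <- vp$names
  list(par = par, loglik = sum(ll_fun(par)),
       log_posterior = vp$log_prior(par) + sum(ll_fun(par)),
       convergence = best$convergence)
}

.col_lse <- function(m) {
  # log of column means of exp(m), stable
  mx <- apply(m, 2L, max)
  mx + log(colMeans(exp(sweep(m, 2L, mx))))
}

#' Widely Applicable Information Criterion
#'
#' `-2 * (lppd - p_waic)` from a draw-by-observation pointwise log-likelihood
#' matrix, with the effective-parameter penalty `p_waic` given by the summed
#' posterior variance of the pointwise log-likelihood. The standard error
#' comes from the spread of the pointwise contributions. Warns when any
#' pointwise variance exceeds 0.4 (the penalty becomes unreliable).
#'
#' @param pointwise_loglik Matrix (draws x observations), or a
#'   `posterior_draws` object.
#' @return List with `waic`, `se`, `p_waic`, and `pointwise_elpd`.
#' @export
waic <- function(pointwise_loglik) {
  ll <- if (inherits(pointwise_loglik, "posterior_draws"))
    pointwise_loglik$pointwise_loglik else as.matrix(pointwise_loglik)
  stopifnot(nrow(ll) >= 2L)
  lppd_i <- .col_lse(ll)
  p_i <- apply(ll, 2L, stats::var)
  if (any(p_i > 0.4))
    warning(sum(p_i > 0.4), " observation(s) with pointwise variance > 0.4; ",
            "WAIC penalty may be unreliable", call. = FALSE)
  elpd_i <- lppd_i - p_i
  n <- length(elpd_i)
  list(waic = -2 * sum(elpd_i),
       se = 2 * sqrt(n * stats::var(elpd_i)),
       p_waic = sum(p_i),
       pointwise_elpd = elpd_i)
}

# Generalized-Pareto fit to exceedances (profile-posterior point estimate of
# the shape, regularized), used to smooth the importance-weight tail.
.gpd_fit <- function(x) {
  x <- sort(x)
  m <- length(x)
  if (m < 5L || stats::sd(x) == 0) return(list(k = NaN, sigma = NaN))
  prior_bs <- 3
  mgrid <- 30L + floor(sqrt(m))
  jj <- seq_len(mgrid)
  xstar <- x[max(1L, floor(m / 4 + 0.5))]
  theta <- 1 / x[m] + (1 - sqrt(mgrid / (jj - 0.5))) / prior_bs / xstar
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    m * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(jj, function(j) sum(exp(prof - prof[j])), numeric(1))
  th_hat <- sum(theta * w)
  k <- -mean(log1p(-th_hat * x))
  sigma <- k / th_hat
  # weakly-informative regularization of the shape, stabilizes small tails
  k <- (m * k + 5) / (m + 10)
  list(k = k, sigma = sigma)
}

.gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates exact leave-one-out by importance sampling from the full
#' posterior, with the upper 20% tail of each observation's importance
#' ratios replaced by expected order statistics of a fitted generalized
#' Pareto distribution, and weights truncated at the raw maximum. The
#' per-observation Pareto shape `k` diagnoses reliability (flagged above
#' 0.7).
#'
#' @inheritParams waic
#' @return List with `psis_loo` (-2 * elpd_loo), `se`, `pareto_k` (per
#'   observation), and `pointwise_elpd`.
#' @export
psis_loo <- function(pointwise_loglik) {
  ll <- if (inherits(pointwise_loglik, "posterior_draws"))
    pointwise_loglik$pointwise_loglik else as.matrix(pointwise_loglik)
  stopifnot(nrow(ll) >= 2L)
  s <- nrow(ll); n <- ncol(ll)
  elpd_i <- numeric(n); k_i <- numeric(n)
  n_tail <- ceiling(0.2 * s)
  for (i in seq_len(n)) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    if (n_tail >= 5L && stats::sd(lw) > 0) {
      ord <- order(lw)
      tail_idx <- ord[(s - n_tail + 1L):s]
      cutoff <- exp(lw[ord[s - n_tail]])
      exceed <- exp(lw[tail_idx]) - cutoff
      fit <- .gpd_fit(exceed)
      if (is.finite(fit$k)) {
        qq <- vapply((seq_len(n_tail) - 0.5) / n_tail, .gpd_quantile,
                     numeric(1), k = fit$k, sigma = fit$sigma)
        lw_max <- max(lw)
        lw[tail_idx[order(exp(lw[tail_idx]))]] <-
          pmin(log(qq + cutoff), lw_max)
        k_i[i] <- fit$k
      } else k_i[i] <- NaN
    } else k_i[i] <- NaN
    # elpd_loo_i = log( sum_s w_s p(y_i | theta_s) / sum_s w_s )
    a <- lw + ll[, i]
    ma <- max(a)
    elpd_i[i] <- ma + log(sum(exp(a - ma))) -
      (max(lw) + log(sum(exp(lw - max(lw)))))
  }
  if (any(is.finite(k_i) & k_i > 0.7))
    warning(sum(k_i > 0.7, na.rm = TRUE),
            " observation(s) with Pareto k > 0.7; PSIS-LOO estimate may be ",
            "unreliable", call. = FALSE)
  list(psis_loo = -2 * sum(elpd_i),
       se = 2 * sqrt(n * stats::var(elpd_i)),
       pareto_k = k_i,
       pointwise_elpd = elpd_i)
}

#' k-fold cross-validated parameter fits
#'
#' Partitions participants into `k` seeded folds, fits the variant by MAP on
#' each training set, and returns the per-fold estimates and their mean
#' (the cross-validated parameter estimate used for averaged belief curves).
#'
#' @inheritParams map_estimate
#' @param k Number of folds (default 10; `k = n` gives leave-one-out).
#' @return List with `fits` (fold x parameter data frame) and `mean` (named
#'   vector of fold-averaged estimates).
#' @export
kfold_cv <- function(records, variant, k = 10L, seed = 1L, lengths = 1:9) {
  records <- validate_participants(records)
  n <- nrow(records)
  stopifnot(n >= k, k >= 2L)
  vp <- variant_parameters(variant)
  if (floor(n - n / k) < length(vp$names))
    stop("training folds smaller than the parameter count", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  fits <- lapply(seq_len(k), function(f)
    map_estimate(records[fold != f, , drop = FALSE], variant,
                 seed = seed + f, lengths = lengths)$par)
  fits <- as.data.frame(do.call(rbind, fits))
  list(fits = cbind(fold = seq_len(k), fits),
       mean = colMeans(fits))
}

.variant_family <- function(variant) {
  c(aa_hom = "A&A", mas_hom = "MAS", mas_het = "MAS",
    rsa_hom = "RSA", rsa_het = "RSA", rsa_speaker = "RSA")[[variant]]
}

.variant_flavor <- function(variant) {
  c(aa_hom = "Homogeneous", mas_hom = "Homogeneous",
    mas_het = "Heterogeneous", rsa_hom = "Homogeneous",
    rsa_het = "Heterogeneous", rsa_speaker = "Speaker-dependent")[[variant]]
}

#' Compare all model variants on one dataset
#'
#' Fits each variant by maximum likelihood (the `loglik` column) and by MCMC
#' (shared seeding scheme), and reports WAIC and PSIS-LOO with standard
#' errors — the model-comparison table of the analysis.
#'
#' @inheritParams run_mcmc
#' @param variants Variant labels to include (default: all six).
#' @param file Optional CSV output path.
#' @return Data frame of class `model_comparison` with columns `model`,
#'   `variant`, `loglik`, `waic`, `waic_se`, `psis_loo`, `psis_loo_se`.
#' @export
compare_models <- function(records, variants = MODEL_VARIANTS,
                           config = mcmc_config(), lengths = 1:9,
                           file = NULL) {
  records <- validate_participants(records)
  rows <- lapply(variants, function(v) {
    ml <- map_estimate(records, v, use_prior = FALSE, seed = config$seed,
                       lengths = lengths)
    post <- run_mcmc(records, v, config, lengths)
    w <- waic(post)
    l <- psis_loo(post)
    data.frame(model = .variant_family(v), variant = v,
               loglik = ml$loglik,
               waic = w$waic, waic_se = w$se,
               psis_loo = l$psis_loo, psis_loo_se = l$se)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("model_comparison", class(out))
  if (!is.null(file))
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  out
}
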