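# End-to-end orchestration: generate data, reproduce the simulation figures,
# fit variants, and emit the model-comparison table. Each command writes its
# results (plus a run.json embedding the seed and configuration) into an
# output directory and logs one structured line per stage to stderr.

.log_stage <- function(stage, seed, n, t0) {
  message(sprintf("stage=%s seed=%d n=%d elapsed=%.1fs",
                  stage, seed, n, as.numeric(Sys.time()) - t0))
}

.write_run_json <- function(out_dir, command, seed, config) {
  jsonlite::write_json(
    list(command = command, seed = seed, config = config,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
}

#' Read a run configuration file
#'
#' YAML or JSON, decided by file extension.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

.resolve_records <- function(data) {
  if (is.character(data)) read_participants(data) else
    validate_participants(data)
}

#' Reproduce the model-simulation tables
#'
#' Writes `effect_grid.csv` (the persuasion-bias by evidence-strength
#' effect-size grid) and `belief_curves.csv` (literal J0 and pragmatic J1
#' belief curves as a function of evidence, at a given bias and response
#' offset). The effect grid defaults to the wider 1..10 stick range of the
#' published simulation figure; the belief curves use the behavioral task's
#' 1..9 range.
#'
#' @param out Output directory (created if needed).
#' @param beta_values Persuasion biases for the grid.
#' @param utterances Evidence lengths for the grid.
#' @param grid_lengths Stick-length support for the grid (default `1:10`).
#' @param curve_beta Bias for the pragmatic belief curve (default 2.03, the
#'   cross-validated average fit).
#' @param curve_offset Response offset for the curves (default -0.13).
#' @param seed Recorded in `run.json` (the command is deterministic).
#' @return Invisible list with both tables.
#' @export
cmd_simulate <- function(out = "results", beta_values = c(0, 1, 2, 10, 100),
                         utterances = 6:9, grid_lengths = 1:10,
                         curve_beta = 2.03, curve_offset = -0.13, seed = 1L) {
  t0 <- as.numeric(Sys.time())
  if (length(beta_values) == 0L || length(utterances) == 0L)
    stop("empty simulation grid", call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  grid <- simulation_grid(beta_values, utterances, "longer",
                          lengths = grid_lengths,
                          file = file.path(out, "effect_grid.csv"))
  rp <- response_params(offset = curve_offset)
  curves <- data.frame(
    utterance = 1:9,
    j0 = vapply(1:9, function(u)
      predicted_slider(literal_listener(u), rp), numeric(1)),
    j1 = vapply(1:9, function(u)
      predicted_slider(pragmatic_listener(u, "longer",
                                          speaker_params(curve_beta)), rp),
      numeric(1)))
  utils::write.csv(curves, file.path(out, "belief_curves.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_run_json(out, "simulate", seed,
                  list(beta_values = beta_values, utterances = utterances,
                       grid_lengths = range(grid_lengths),
                       curve_beta = curve_beta, curve_offset = curve_offset))
  .log_stage("simulate", seed, nrow(grid), t0)
  invisible(list(effect_grid = grid, belief_curves = curves))
}

#' Generate a synthetic participant CSV
#'
#' @param out Output directory.
#' @param config A [generator_config()].
#' @return Invisibly, the generated table.
#' @export
cmd_generate <- function(out = "results", config = generator_config()) {
  t0 <- as.numeric(Sys.time())
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  d <- generate_dataset(config)
  write_participants(d, file.path(out, "participants.csv"))
  .write_run_json(out, "generate", config$seed,
                  config[setdiff(names(config), "response")])
  .log_stage("generate", config$seed, nrow(d), t0)
  invisible(d)
}

#' Fit one model variant to a participant table
#'
#' Runs MAP estimation and MCMC, writing the posterior draws
#' (`posterior_draws.csv`: draw, chain, param, value), and a `summary.json`
#' with the MAP estimate, posterior means and 95% intervals, the per-group
#' mixture weights (speaker-dependent variant), and R-hat diagnostics.
#'
#' @param data Participant CSV path or data frame.
#' @param variant Model variant label.
#' @param out Output directory.
#' @param config An [mcmc_config()].
#' @return Invisibly, a list with the `posterior_draws` object and the MAP
#'   fit.
#' @export
cmd_fit <- function(data, variant = "rsa_speaker", out = "results",
                    config = mcmc_config()) {
  t0 <- as.numeric(Sys.time())
  records <- .resolve_records(data)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  map <- map_estimate(records, variant, seed = config$seed)
  post <- run_mcmc(records, variant, config)
  long <- data.frame(draw = rep(seq_len(nrow(post$draws)),
                                times = ncol(post$draws)),
                     chain = rep(post$chain_ids, times = ncol(post$draws)),
                     param = rep(colnames(post$draws),
                                 each = nrow(post$draws)),
                     value = as.vector(post$draws))
  utils::write.csv(long, file.path(out, "posterior_draws.csv"),
                   row.names = FALSE, quote = FALSE)
  sm <- summary(post)
  summary_list <- list(
    variant = variant, seed = config$seed, n = nrow(records),
    map = as.list(map$par), loglik_at_map = map$loglik,
    posterior_mean = as.list(stats::setNames(sm$mean, sm$parameter)),
    ci95_lower = as.list(stats::setNames(sm$lower, sm$parameter)),
    ci95_upper = as.list(stats::setNames(sm$upper, sm$parameter)),
    rhat = as.list(stats::setNames(sm$rhat, sm$parameter)),
    accept_rate = post$accept_rate)
  jsonlite::write_json(summary_list, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_run_json(out, "fit", config$seed,
                  list(variant = variant, mcmc = unclass(config)))
  .log_stage("fit", config$seed, nrow(records), t0)
  invisible(list(posterior = post, map = map))
}

#' Run the full model comparison on a participant table
#'
#' @inheritParams cmd_fit
#' @param variants Variant labels (default: all six).
#' @return Invisibly, the comparison table.
#' @export
cmd_compare <- function(data, out = "results", variants = MODEL_VARIANTS,
                        config = mcmc_config()) {
  t0 <- as.numeric(Sys.time())
  records <- .resolve_records(data)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tab <- compare_models(records, variants, config,
                        file = file.path(out, "comparison.csv"))
  .write_run_json(out, "compare", config$seed,
                  list(variants = variants, mcmc = unclass(config)))
  .log_stage("compare", config$seed, nrow(records), t0)
  invisible(tab)
}
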