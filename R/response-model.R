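# Mapping model beliefs to slider responses and per-participant likelihoods
# for the six model variants compared in the analysis:
#
#   aa_hom       simple anchor-and-adjust (eta = .5, R = 0), whole population
#   mas_hom      minimum-acceptable-strength (free eta, R), whole population
#   mas_het      mixture of the simple AA and MAS rules
#   rsa_hom      pragmatic listener J1 for the whole population
#   rsa_het      mixture of literal (J0) and pragmatic (J1) listeners
#   rsa_speaker  J0/J1 mixture with independent weights per speaker-phase
#                sub-group (keyed by the priority rank of the stick the
#                participant expected the contestant to show first)
#
# Responses are modeled as Gaussian on the probability scale (slider / 100)
# around the variant's predicted probability; latent group assignments are
# marginalized analytically.

MODEL_VARIANTS <- c("aa_hom", "mas_hom", "mas_het",
                    "rsa_hom", "rsa_het", "rsa_speaker")

#' The speaker-phase candidate sticks
#'
#' The example stick set shown in the speaker-expectation phase.
#' @return Integer vector `c(2, 4, 7, 8, 9)`.
#' @export
speaker_phase_sticks <- function() c(2L, 4L, 7L, 8L, 9L)

#' Response parameters
#'
#' @param offset Additive shift on the probability scale, applied before
#'   clipping; a negative offset translates the whole response curve down.
#' @param noise_sd Standard deviation of Gaussian response noise on the
#'   probability scale (slider / 100).
#' @return An object of class `response_params`.
#' @export
response_params <- function(offset = 0, noise_sd = 0.18) {
  stopifnot(is.numeric(offset), length(offset) == 1L,
            offset >= -1, offset <= 1,
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd > 0)
  structure(list(offset = offset, noise_sd = noise_sd),
            class = "response_params")
}

#' Predicted slider response from a verdict belief
#'
#' `100 * clip(p_longer + offset, 0, 1)`.
#'
#' @param belief A [verdict_belief()] (or a bare probability of "longer").
#' @param params A [response_params()]; only the offset is used.
#' @return Predicted slider position in `[0, 100]`.
#' @export
#' @examples
#' predicted_slider(verdict_belief(0.5), response_params(offset = -0.13)) # 37
predicted_slider <- function(belief, params = response_params()) {
  p <- if (inherits(belief, "verdict_belief")) belief[["longer"]] else belief
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1),
            inherits(params, "response_params"))
  100 * pmin(pmax(p + params$offset, 0), 1)
}

# mirror a stick length through the midpoint (agenda-relative orientation)
.mirror_u <- function(u, lengths = 1:9) {
  as.integer(min(lengths) + max(lengths) - u)
}

# Predicted probability-scale response for each record under one judge model.
# judge: "J0" (literal), "J1" (pragmatic; needs beta), "AA"/"MAS" (needs
# eta/anchor). The short-biased contestant's evidence is mapped through the
# mirrored length so the anchor applies to agenda-relative strength.
.judge_probs <- function(records, judge, beta = NULL, eta = NULL,
                         anchor = NULL, lengths = 1:9) {
  ss <- stick_state_space(lengths)
  iu <- match(records$evidence1, ss$lengths)
  is_long <- records$first_contestant == "longer"
  switch(judge,
    J0 = unname(ss$l0_longer[iu]),
    J1 = {
      cl <- .pragmatic_curve(beta, "longer", ss)
      cs <- .pragmatic_curve(beta, "shorter", ss)
      unname(ifelse(is_long, cl[iu], cs[iu]))
    },
    AA = ,
    MAS = {
      pars <- if (judge == "AA") aa_params() else aa_params(eta, anchor)
      u_rel <- ifelse(is_long, records$evidence1,
                      .mirror_u(records$evidence1, ss$lengths))
      b <- aa_update(0.5, u_rel, pars, ss$lengths)
      ifelse(is_long, b, 1 - b)
    },
    stop("unknown judge model: ", judge, call. = FALSE)
  )
}

# Gaussian log-density of the observed sliders around a component's prediction
.component_ll <- function(records, probs, offset, noise_sd) {
  pred <- pmin(pmax(probs + offset, 0), 1)
  stats::dnorm(records$slider1 / 100, mean = pred, sd = noise_sd, log = TRUE)
}

# log(w exp(la) + (1 - w) exp(lb)), elementwise, numerically stable
.mix_ll <- function(la, lb, w) {
  m <- pmax(la, lb)
  m + log(w * exp(la - m) + (1 - w) * exp(lb - m))
}

.check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% MODEL_VARIANTS)
    stop("unknown variant label; must be one of: ",
         paste(MODEL_VARIANTS, collapse = ", "), call. = FALSE)
  variant
}

# parameter-name table per variant; rsa_speaker weights are keyed by the
# agenda-relative priority rank of the rank-1 stick (1 = strongest)
.variant_par_names <- function(variant) {
  switch(.check_variant(variant),
    aa_hom      = c("offset", "noise_sd"),
    mas_hom     = c("eta", "anchor", "offset", "noise_sd"),
    mas_het     = c("eta", "anchor", "weight", "offset", "noise_sd"),
    rsa_hom     = c("beta", "offset", "noise_sd"),
    rsa_het     = c("beta", "weight", "offset", "noise_sd"),
    rsa_speaker = c("beta", paste0("w_rank", 1:5), "offset", "noise_sd"))
}

#' Agenda-relative priority rank of a speaker-phase choice
#'
#' Maps the stick a participant expected a contestant to show first to its
#' rank in that contestant's persuasive preference order over the candidate
#' set {2, 4, 7, 8, 9}: rank 1 is the most persuasive stick (9 for a
#' long-biased contestant, 2 for a short-biased one), rank 5 the least. The
#' two counterbalanced contestant orders are thereby pooled onto one scale.
#'
#' @param stick Chosen stick(s) from the candidate set.
#' @param first_contestant `"longer"` or `"shorter"` (vectorized).
#' @return Integer rank(s) in 1..5.
#' @export
speaker_choice_rank <- function(stick, first_contestant) {
  cand <- speaker_phase_sticks()
  stopifnot(all(stick %in% cand),
            all(first_contestant %in% c("longer", "shorter")))
  r_long <- match(stick, rev(cand))         # 9 -> 1 ... 2 -> 5
  r_short <- match(stick, cand)             # 2 -> 1 ... 9 -> 5
  ifelse(first_contestant == "longer", r_long, r_short)
}

# Build a fast pointwise log-likelihood closure for a dataset x variant.
# Returns function(par) -> numeric vector (one entry per record, order-stable).
make_loglik <- function(records, variant, lengths = 1:9) {
  variant <- .check_variant(variant)
  records <- validate_participants(records)
  ss <- stick_state_space(lengths)
  j0 <- .judge_probs(records, "J0", lengths = lengths)
  aa <- .judge_probs(records, "AA", lengths = lengths)
  rank1 <- speaker_choice_rank(records$speaker_rank1,
                               records$first_contestant)
  iu <- match(records$evidence1, ss$lengths)
  is_long <- records$first_contestant == "longer"
  # lengths symmetric about the midpoint => the short-agenda curve is the
  # mirrored complement of the long-agenda curve
  sym <- all(ss$lengths + rev(ss$lengths) == 2 * ss$midpoint)
  cache <- new.env(parent = emptyenv())
  cache$beta <- NA_real_
  j1 <- function(beta) {
    if (!isTRUE(beta == cache$beta)) {
      cl <- .pragmatic_curve(beta, "longer", ss)
      cs <- if (sym) 1 - rev(cl) else .pragmatic_curve(beta, "shorter", ss)
      cache$probs <- unname(ifelse(is_long, cl[iu], cs[iu]))
      cache$beta <- beta
    }
    cache$probs
  }
  function(par) {
    off <- par[["offset"]]; sd <- par[["noise_sd"]]
    switch(variant,
      aa_hom = .component_ll(records, aa, off, sd),
      mas_hom = .component_ll(
        records, .judge_probs(records, "MAS", eta = par[["eta"]],
                              anchor = par[["anchor"]], lengths = lengths),
        off, sd),
      mas_het = {
        lm <- .component_ll(
          records, .judge_probs(records, "MAS", eta = par[["eta"]],
                                anchor = par[["anchor"]], lengths = lengths),
          off, sd)
        la <- .component_ll(records, aa, off, sd)
        .mix_ll(lm, la, par[["weight"]])
      },
      rsa_hom = .component_ll(records, j1(par[["beta"]]), off, sd),
      rsa_het = {
        l1 <- .component_ll(records, j1(par[["beta"]]), off, sd)
        l0 <- .component_ll(records, j0, off, sd)
        .mix_ll(l1, l0, par[["weight"]])
      },
      rsa_speaker = {
        l1 <- .component_ll(records, j1(par[["beta"]]), off, sd)
        l0 <- .component_ll(records, j0, off, sd)
        w <- unname(par[paste0("w_rank", 1:5)])[rank1]
        .mix_ll(l1, l0, w)
      })
  }
}

#' Per-participant log-likelihood under a model variant
#'
#' Gaussian log-density of the participant's slider (on the probability
#' scale) around the variant's predicted response, with mixture variants
#' marginalizing the latent judge assignment analytically. The
#' speaker-dependent variant selects the mixture weight keyed by the
#' participant's speaker-phase choice (see [speaker_choice_rank()]).
#'
#' @param record A single participant record (one-row data frame with the
#'   participant CSV schema).
#' @param variant One of `"aa_hom"`, `"mas_hom"`, `"mas_het"`, `"rsa_hom"`,
#'   `"rsa_het"`, `"rsa_speaker"`.
#' @param params Named list or vector of the variant's parameters (see
#'   [variant_parameters()]).
#' @inheritParams stick_state_space
#' @return The log-likelihood (a single number).
#' @export
participant_loglik <- function(record, variant, params, lengths = 1:9) {
  stopifnot(nrow(record) == 1L)
  dataset_loglik(record, variant, params, lengths)$pointwise[[1L]]
}

#' Dataset log-likelihood under a model variant
#'
#' @param records A participant table (see [read_participants()]).
#' @inheritParams participant_loglik
#' @return A list with `total` (sum) and `pointwise` (per-record vector in
#'   table order).
#' @export
dataset_loglik <- function(records, variant, params, lengths = 1:9) {
  if (nrow(records) == 0L) stop("empty record table", call. = FALSE)
  par <- unlist(params)
  need <- .variant_par_names(variant)
  missing <- setdiff(need, names(par))
  if (length(missing) > 0L)
    stop("missing parameter(s) for variant '", variant, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  ll <- make_loglik(records, variant, lengths)(par)
  list(total = sum(ll), pointwise = ll)
}

#' Parameter names, bounds and priors of a model variant
#'
#' The free parameters of each variant, with box bounds and the log prior
#' density used for Bayesian fitting: persuasion bias
#' `beta ~ Uniform(0, 10)`, response `offset ~ Uniform(-0.5, 0.5)`,
#' `noise_sd ~ half-normal(0.3)`, mixture weights and the adjustment weight
#' `eta ~ Uniform(0, 1)`, and the MAS `anchor ~ Uniform(-1, 1)`.
#'
#' @inheritParams participant_loglik
#' @return A list with `names`, `lower`, `upper`, and `log_prior(par)`.
#' @export
variant_parameters <- function(variant) {
  nm <- .variant_par_names(variant)
  lower <- vapply(nm, function(p) switch(sub("[0-9]+$", "", p),
    beta = 0, offset = -0.5, noise_sd = 1e-3, eta = 0, anchor = -1,
    weight = 0, w_rank = 0), numeric(1))
  upper <- vapply(nm, function(p) switch(sub("[0-9]+$", "", p),
    beta = 10, offset = 0.5, noise_sd = 2, eta = 1, anchor = 1,
    weight = 1, w_rank = 1), numeric(1))
  log_prior <- function(par) {
    par <- par[nm]
    if (any(par < lower | par > upper)) return(-Inf)
    lp <- 0
    if ("noise_sd" %in% nm)
      lp <- lp + stats::dnorm(par[["noise_sd"]], 0, 0.3, log = TRUE)
    lp  # uniform terms are constant inside the box
  }
  list(names = nm, lower = lower, upper = upper, log_prior = log_prior)
}
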