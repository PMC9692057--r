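# Literal listener, motivated speaker, and skeptical pragmatic listener,
# computed by exact enumeration over the Stick Contest state space.

#' Construct a verdict belief
#'
#' Probability mass over the binary verdict {longer, shorter}.
#'
#' @param p_longer Probability that the average stick length exceeds the
#'   midpoint.
#' @return An object of class `verdict_belief`: a named numeric vector with
#'   components `longer` and `shorter` summing to 1.
#' @export
verdict_belief <- function(p_longer) {
  stopifnot(is.numeric(p_longer), length(p_longer) == 1L,
            p_longer >= 0, p_longer <= 1)
  structure(c(longer = p_longer, shorter = 1 - p_longer),
            class = "verdict_belief")
}

#' @export
print.verdict_belief <- function(x, ...) {
  cat(sprintf("verdict belief: P(longer) = %.4f, P(shorter) = %.4f\n",
              x[["longer"]], x[["shorter"]]))
  invisible(x)
}

#' Speaker parameters
#'
#' @param beta Nonnegative persuasion bias: the weight the speaker places on
#'   persuasive utility. `beta = 0` recovers the neutral epistemic speaker.
#'   The soft-max temperature is absorbed into `beta` (their product is the
#'   single identifiable parameter), so no separate temperature is exposed.
#' @param epsilon Probability mass a literal listener reserves for worlds that
#'   violate the utterance's semantics. In the Stick Contest the speaker can
#'   only reveal actual sticks, so the default (and in-task value) is 0; the
#'   field exists for generality.
#' @return An object of class `speaker_params`.
#' @export
speaker_params <- function(beta, epsilon = 0) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0,
            is.numeric(epsilon), length(epsilon) == 1L,
            epsilon >= 0, epsilon < 1)
  structure(list(beta = beta, epsilon = epsilon), class = "speaker_params")
}

#' Literal listener
#'
#' The base case of the social recursion: a listener who takes the revealed
#' stick at face value. The revealed length is treated as one of the world's
#' sticks and the remaining sticks follow the i.i.d.-uniform prior; worlds
#' whose mean falls exactly on the midpoint are excluded and the verdict
#' belief renormalized over {longer, shorter}, which yields a prior belief of
#' exactly 1/2 by symmetry.
#'
#' @param u Revealed stick length.
#' @inheritParams stick_state_space
#' @param epsilon Mass reserved for semantics-violating worlds (default 0; see
#'   [speaker_params()]).
#' @return A [verdict_belief()].
#' @export
#' @examples
#' literal_listener(5)  # exactly 0.5 by symmetry
#' literal_listener(9)  # strong evidence for "longer"
literal_listener <- function(u, lengths = 1:9, epsilon = 0) {
  ss <- stick_state_space(lengths)
  u <- check_utterance(u, ss$lengths)
  p <- ss$l0_longer[[as.character(u)]]
  if (epsilon > 0) {
    # blend with the unconditioned prior (which is 1/2 after tie exclusion)
    p <- (1 - epsilon) * p + epsilon * 0.5
  }
  verdict_belief(p)
}

#' Persuasive utility of an utterance
#'
#' The log-probability the literal listener assigns to the speaker's agenda
#' after seeing the utterance. Strictly increasing in stick length for the
#' "longer" agenda and strictly decreasing for "shorter".
#'
#' @param u Revealed stick length.
#' @param agenda `"longer"` or `"shorter"`: the verdict the speaker is
#'   rewarded for inducing.
#' @inheritParams stick_state_space
#' @return log L0(agenda | u), a negative real.
#' @export
#' @examples
#' persuasive_utility(5, "longer")  # log(0.5)
persuasive_utility <- function(u, agenda, lengths = 1:9) {
  agenda <- check_agenda(agenda)
  b <- literal_listener(u, lengths)
  p <- b[[agenda]]
  if (p <= 0)
    stop("degenerate semantics: literal listener assigns zero mass to the ",
         "agenda", call. = FALSE)
  log(p)
}

# speaker choice probabilities over the length alphabet for every world at
# once; row w, column u: S(u | w, agenda, beta), zero when u is not in w.
# Computed in ratio form so that arbitrarily large beta is stable.
.speaker_matrix <- function(beta, agenda, ss) {
  lam <- if (agenda == "longer") log(ss$l0_longer) else log1p(-ss$l0_longer)
  # exponent clamped below overflow so that dominated utterances underflow to
  # probability ~0 instead of propagating Inf through the matrix product
  e <- exp(pmin(beta * outer(lam, lam, "-"), 700))

  d <- ss$counts %*% e                        # d[w, u] = sum_i c_wi e[i, u]
  s <- ss$counts / d                          # c_wu / d_wu
  s[!is.finite(s)] <- 0
  s
}

#' Motivated speaker's choice distribution
#'
#' A contestant with a persuasive agenda chooses which of the world's 5 actual
#' sticks to reveal, with probability proportional to
#' `exp(beta * persuasive_utility)` across the sticks (soft-max). Because only
#' true sticks can be shown, the epistemic term is constant across choices and
#' drops out. At `beta = 0` the distribution is uniform over the 5 sticks; as
#' `beta` grows it concentrates on the most persuasive stick.
#'
#' @param world Integer vector of 5 stick lengths.
#' @inheritParams persuasive_utility
#' @param params A [speaker_params()].
#' @return A named numeric vector of probabilities over the world's distinct
#'   stick lengths (duplicated sticks pooled), summing to 1.
#' @export
#' @examples
#' speaker_distribution(c(2, 4, 7, 8, 9), "longer", speaker_params(2))
speaker_distribution <- function(world, agenda, params, lengths = 1:9) {
  ss <- stick_state_space(lengths)
  world <- check_world(world, ss$lengths)
  agenda <- check_agenda(agenda)
  stopifnot(inherits(params, "speaker_params"))
  cc <- tabulate(match(world, ss$lengths), nbins = length(ss$lengths))
  lam <- if (agenda == "longer") log(ss$l0_longer) else log1p(-ss$l0_longer)
  present <- which(cc > 0L)
  # per-slot soft-max in ratio form, pooled over duplicate lengths
  p <- vapply(present, function(i) {
    cc[i] / sum(cc[present] * exp(params$beta * (lam[present] - lam[i])))
  }, numeric(1))
  names(p) <- ss$lengths[present]
  p
}

# Pragmatic-listener belief P(longer | u) for every utterance at once.
# Worlds are weighted by prior x speaker likelihood; ties excluded.
.pragmatic_curve <- function(beta, agenda, ss) {
  s <- .speaker_matrix(beta, agenda, ss)
  m <- s * ss$mult
  vl <- colSums(m[ss$verdict == "longer", , drop = FALSE])
  vs <- colSums(m[ss$verdict == "shorter", , drop = FALSE])
  p <- vl / (vl + vs)
  names(p) <- ss$lengths
  p
}

#' Skeptical pragmatic listener
#'
#' Inverts the motivated-speaker model: the posterior over worlds is
#' proportional to the speaker's probability of revealing `u` times the
#' uniform world prior, enumerated exactly and marginalized to the verdict
#' (ties excluded as in [literal_listener()]). With `beta = 0` this reduces to
#' the literal listener; with large `beta`, weak favourable evidence backfires
#' because a strongly motivated speaker would have shown something stronger.
#'
#' @inheritParams persuasive_utility
#' @param params A [speaker_params()]; `params$beta` is the persuasion bias
#'   the listener attributes to the speaker.
#' @return A [verdict_belief()].
#' @export
#' @examples
#' pragmatic_listener(6, "longer", speaker_params(2))   # weak evidence discounted
#' pragmatic_listener(6, "longer", speaker_params(0))   # literal listener
pragmatic_listener <- function(u, agenda, params, lengths = 1:9) {
  ss <- stick_state_space(lengths)
  u <- check_utterance(u, ss$lengths)
  agenda <- check_agenda(agenda)
  stopifnot(inherits(params, "speaker_params"))
  p <- .pragmatic_curve(params$beta, agenda, ss)[[as.character(u)]]
  verdict_belief(p)
}

#' Size of the weak evidence effect
#'
#' The decrease in belief in a proposition after seeing evidence that
#' nominally supports it: prior belief (1/2) minus the pragmatic listener's
#' posterior belief in the agenda. Positive values mean the evidence
#' backfired.
#'
#' @inheritParams pragmatic_listener
#' @return A real number in (-1/2, 1/2); positive = backfire.
#' @export
#' @examples
#' effect_size(6, "longer", speaker_params(2))    # positive: 6'' backfires
#' effect_size(6, "longer", speaker_params(0))    # negative: taken at face value
effect_size <- function(u, agenda, params, lengths = 1:9) {
  ss <- stick_state_space(lengths)
  u <- check_utterance(u, ss$lengths)
  agenda <- check_agenda(agenda)
  supports <- (agenda == "longer" && u > ss$midpoint) ||
    (agenda == "shorter" && u < ss$midpoint)
  if (!supports)
    stop("unsupported evidence: u = ", u, " does not favor the '", agenda,
         "' agenda", call. = FALSE)
  post <- pragmatic_listener(u, agenda, params, lengths)[[agenda]]
  0.5 - post
}

#' Effect-size grid over persuasion bias and evidence strength
#'
#' Tabulates [effect_size()] over the cross product of `beta_values` and
#' `utterances`, reproducing the bias-by-evidence simulation grid. The set of
#' backfiring evidence values is nondecreasing (by inclusion) in `beta`.
#'
#' @param beta_values Nonnegative persuasion biases.
#' @param utterances Evidence lengths; each must favor `agenda`.
#' @inheritParams pragmatic_listener
#' @param file Optional path; when given, the table is also written as CSV.
#' @return A data frame with columns `beta`, `utterance`, `agenda`,
#'   `effect_size`.
#' @export
#' @examples
#' simulation_grid(c(0, 1, 10, 100), 6:9)
simulation_grid <- function(beta_values, utterances, agenda = "longer",
                            lengths = 1:9, file = NULL) {
  stopifnot(length(beta_values) >= 1L, length(utterances) >= 1L)
  agenda <- check_agenda(agenda)
  out <- expand.grid(utterance = as.integer(utterances),
                     beta = as.numeric(beta_values),
                     KEEP.OUT.ATTRS = FALSE)
  out$agenda <- agenda
  out$effect_size <- mapply(function(u, b)
    effect_size(u, agenda, speaker_params(b), lengths),
    out$utterance, out$beta)
  out <- out[, c("beta", "utterance", "agenda", "effect_size")]
  if (!is.null(file))
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  out
}
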