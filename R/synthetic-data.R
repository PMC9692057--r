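# Synthetic participants with the two-phase experimental structure: a
# speaker-expectation phase (rank the candidate sticks a contestant would
# show) and a listener-judgment phase (slider belief report after one piece
# of evidence). The generator's defaults emulate the study conditions: 723
# participants, 67% pragmatic responders, generating persuasion bias 2.26,
# counterbalanced contestant order, and oversampled weak evidence.

#' Generator configuration
#'
#' @param n_participants Number of synthetic participants (default 723, the
#'   post-exclusion sample size).
#' @param p_pragmatic Probability a participant is a pragmatic (J1) responder
#'   rather than a literal (J0) responder (default 0.67).
#' @param beta_true Generating persuasion bias for pragmatic responders
#'   (default 2.26).
#' @param response A [response_params()]; `offset` shifts every response and
#'   `noise_sd` scales the Gaussian slider noise (probability scale).
#' @param strength_weights Sampling weights over the four evidence-strength
#'   conditions (distance 1..4 from the midpoint). The default
#'   `c(0.4, 0.2, 0.2, 0.2)` oversamples the weak-evidence condition.
#' @param hedging Speaker-phase policy for literal responders:
#'   `"weaker-first"` (default; rank-1 chosen uniformly among the four
#'   non-strongest candidate sticks, so the strongest-expected group contains
#'   exactly the pragmatic responders) or `"uniform"` (fully random ranking).
#' @param seed Integer seed; every run is fully reproducible from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 723L,
                             p_pragmatic = 0.67,
                             beta_true = 2.26,
                             response = response_params(offset = 0,
                                                        noise_sd = 0.18),
                             strength_weights = c(0.4, 0.2, 0.2, 0.2),
                             hedging = c("weaker-first", "uniform"),
                             seed = 1L) {
  stopifnot(n_participants >= 0L,
            p_pragmatic >= 0, p_pragmatic <= 1,
            beta_true >= 0,
            inherits(response, "response_params"),
            length(strength_weights) == 4L,
            all(strength_weights >= 0), sum(strength_weights) > 0)
  structure(list(n_participants = as.integer(n_participants),
                 p_pragmatic = p_pragmatic, beta_true = beta_true,
                 response = response,
                 strength_weights = strength_weights / sum(strength_weights),
                 hedging = match.arg(hedging), seed = as.integer(seed)),
            class = "generator_config")
}

#' Sample the between-subjects design
#'
#' Contestant order is counterbalanced (exactly half of participants see the
#' long-biased contestant first, up to rounding, in shuffled order) and the
#' first evidence value is drawn from {6,7,8,9} (long first) or {4,3,2,1}
#' (short first) according to the strength weights.
#'
#' @param config A [generator_config()]. Uses the current RNG state; seed it
#'   (or call via [generate_dataset()]) for reproducibility.
#' @return Data frame with columns `first_contestant` and `evidence1`.
#' @export
sample_design <- function(config = generator_config()) {
  n <- config$n_participants
  fc <- sample(rep(c("longer", "shorter"), length.out = n))
  strength <- sample(1:4, n, replace = TRUE, prob = config$strength_weights)
  evidence <- ifelse(fc == "longer", 5L + strength, 5L - strength)
  data.frame(first_contestant = fc, evidence1 = as.integer(evidence))
}

#' Simulate one speaker-expectation response
#'
#' A pragmatic responder ranks the candidate sticks {2,4,7,8,9} by descending
#' persuasive utility for the contestant's agenda (9 first for a long-biased
#' contestant, 2 first for a short-biased one). A literal responder hedges:
#' under `"weaker-first"` the rank-1 stick is uniform over the four
#' non-strongest candidates (remaining ranks shuffled); under `"uniform"` the
#' whole ranking is a uniform permutation.
#'
#' @param type `"pragmatic"` or `"literal"`.
#' @param contestant Contestant agenda, `"longer"` or `"shorter"`.
#' @param hedging Hedging policy for literal responders.
#' @return Integer vector: the five candidate sticks in claimed priority
#'   order.
#' @export
simulate_speaker_phase <- function(type = c("pragmatic", "literal"),
                                   contestant = c("longer", "shorter"),
                                   hedging = c("weaker-first", "uniform")) {
  type <- match.arg(type)
  contestant <- match.arg(contestant)
  hedging <- match.arg(hedging)
  cand <- speaker_phase_sticks()
  if (type == "pragmatic") {
    util <- vapply(cand, persuasive_utility, numeric(1), agenda = contestant)
    return(cand[order(util, decreasing = TRUE)])
  }
  if (hedging == "uniform") return(sample(cand))
  strongest <- if (contestant == "longer") max(cand) else min(cand)
  rest <- setdiff(cand, strongest)
  first <- sample(rest, 1L)
  c(first, sample(c(setdiff(rest, first), strongest)))
}

#' Simulate one listener-judgment response
#'
#' A pragmatic responder's belief is the skeptical pragmatic listener's
#' posterior at `beta_true` (knowing the revealing contestant's agenda); a
#' literal responder uses the literal listener. The slider is the predicted
#' response plus Gaussian noise (sd `noise_sd * 100` slider points), clipped
#' to `[0, 100]`.
#'
#' @inheritParams simulate_speaker_phase
#' @param evidence First revealed stick length.
#' @param beta_true Persuasion bias attributed to the contestant.
#' @param response A [response_params()].
#' @return Slider value in `[0, 100]`.
#' @export
simulate_listener_phase <- function(type = c("pragmatic", "literal"),
                                    contestant = c("longer", "shorter"),
                                    evidence, beta_true = 2.26,
                                    response = response_params()) {
  type <- match.arg(type)
  contestant <- match.arg(contestant)
  belief <- if (type == "pragmatic")
    pragmatic_listener(evidence, contestant, speaker_params(beta_true))
  else literal_listener(evidence)
  pred <- predicted_slider(belief, response)
  pmin(pmax(pred + stats::rnorm(1L, 0, response$noise_sd * 100), 0), 100)
}

#' Generate a synthetic participant table
#'
#' Composes the two phases per participant with a shared contestant order.
#' Latent responder types are drawn with probability `p_pragmatic`; the
#' derived `group` column marks participants whose rank-1 speaker-phase
#' choice is the contestant's most persuasive stick. A placeholder
#' `evidence2` column (the second contestant's evidence) is generated for
#' schema completeness but never modeled.
#'
#' @param config A [generator_config()].
#' @return Participant table (validated; includes `group`, the latent `type`,
#'   and the unmodeled `evidence2`).
#' @export
#' @examples
#' d <- generate_dataset(generator_config(n_participants = 20, seed = 7))
#' table(d$group)
generate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_participants
  if (n == 0L) {
    out <- data.frame(id = character(), first_contestant = character(),
                      speaker_rank1 = integer(), evidence1 = integer(),
                      slider1 = numeric())
    out$group <- character(); out$type <- character()
    out$evidence2 <- integer()
    return(out)
  }
  design <- sample_design(config)
  type <- ifelse(stats::runif(n) < config$p_pragmatic, "pragmatic", "literal")

  # listener beliefs vectorized over the few distinct (evidence, contestant)
  # cells rather than per participant
  ss <- stick_state_space()
  cl <- .pragmatic_curve(config$beta_true, "longer", ss)
  cs <- .pragmatic_curve(config$beta_true, "shorter", ss)
  iu <- match(design$evidence1, ss$lengths)
  is_long <- design$first_contestant == "longer"
  p1 <- ifelse(is_long, cl[iu], cs[iu])          # pragmatic responders
  p0 <- unname(ss$l0_longer[iu])                 # literal responders
  p <- ifelse(type == "pragmatic", p1, p0)
  pred <- predicted_slider(p, config$response)
  slider <- pmin(pmax(pred + stats::rnorm(n, 0, config$response$noise_sd * 100),
                      0), 100)

  rank1 <- vapply(seq_len(n), function(i)
    simulate_speaker_phase(type[i], design$first_contestant[i],
                           config$hedging)[1L], integer(1))

  # unmodeled second piece of evidence, from the other contestant's set
  evidence2 <- ifelse(is_long, 5L - sample(1:4, n, replace = TRUE),
                      5L + sample(1:4, n, replace = TRUE))

  out <- data.frame(id = sprintf("p%04d", seq_len(n)),
                    first_contestant = design$first_contestant,
                    speaker_rank1 = rank1,
                    evidence1 = design$evidence1,
                    slider1 = slider)
  out <- validate_participants(out)
  out$type <- type
  out$evidence2 <- as.integer(evidence2)
  out
}
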