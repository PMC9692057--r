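# Asocial anchor-and-adjust belief updating, the comparison class for the
# pragmatic account. Beliefs shift additively by the gap between the signed
# strength of the evidence and a reference point.

#' Anchor-and-adjust parameters
#'
#' @param eta Adjustment weight in `[0, 1]`.
#' @param anchor Reference point R in `[-1, 1]` on the signed evidence-strength
#'   scale. The simple anchor-and-adjust variant fixes `eta = 0.5, anchor = 0`
#'   (a neutral baseline); the minimum-acceptable-strength (MAS) variant treats
#'   the anchor as free, so weak positive evidence falling short of it acts as
#'   negative evidence.
#' @return An object of class `aa_params`.
#' @export
aa_params <- function(eta = 0.5, anchor = 0) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta >= 0, eta <= 1,
            is.numeric(anchor), length(anchor) == 1L,
            anchor >= -1, anchor <= 1)
  structure(list(eta = eta, anchor = anchor), class = "aa_params")
}

#' Signed strength of a piece of evidence
#'
#' Linear map from stick length to `[-1, 1]`, oriented toward the "longer"
#' verdict: the midpoint maps to 0 and the extremes to -1 and +1.
#' Antisymmetric about the midpoint.
#'
#' @param u Stick length (vectorized).
#' @inheritParams stick_state_space
#' @return Signed strength in `[-1, 1]`.
#' @export
#' @examples
#' evidence_strength(c(3, 5, 9))  # -0.5, 0, 1
evidence_strength <- function(u, lengths = 1:9) {
  u <- as.numeric(u)
  midpoint <- (min(lengths) + max(lengths)) / 2
  (u - midpoint) / (max(lengths) - midpoint)
}

#' Anchor-and-adjust belief update
#'
#' `prior + eta * (s(u) - anchor)`, clipped to `[0, 1]`. The belief scale is
#' oriented toward "longer"; evidence from a short-biased contestant is handled
#' upstream by mirroring the stick length through the midpoint, so one belief
#' scale serves both contestant orders.
#'
#' @param prior Prior belief in `[0, 1]` (vectorized with `u`).
#' @param u Stick length.
#' @param params An [aa_params()].
#' @inheritParams stick_state_space
#' @return Updated belief in `[0, 1]`.
#' @export
#' @examples
#' aa_update(0.5, 6, aa_params())                      # 0.625
#' aa_update(0.5, 6, aa_params(0.5, anchor = 0.5))     # 0.375: backfire
aa_update <- function(prior, u, params = aa_params(), lengths = 1:9) {
  stopifnot(inherits(params, "aa_params"),
            all(prior >= 0 & prior <= 1))
  s <- evidence_strength(u, lengths)
  pmin(pmax(prior + params$eta * (s - params$anchor), 0), 1)
}
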