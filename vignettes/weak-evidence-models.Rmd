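---
title: "Pragmatic models of persuasion in the Stick Contest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pragmatic models of persuasion in the Stick Contest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickcontest)
```

## The problem

Weakly favourable evidence sometimes *backfires*: hearing a weak argument in
favour of a proposition can lower one's belief in it (the weak evidence
effect). This package implements a pragmatic explanation of that effect and
the machinery to test it against asocial alternatives. The intuition is
Gricean: if the arguer is expected to put their best foot forward, showing
weak evidence implies that nothing stronger exists.

The setting is the **Stick Contest**. A set of five hidden sticks has integer
lengths between 1 and 9 inches. A judge must decide whether the sticks'
average length exceeds the 5-inch midpoint. Two contestants — one rewarded if
the judge answers "longer", one if "shorter" — each reveal exactly one of the
five actual sticks. The judge reports a belief on a 0–100 slider.

## The models

Write $w$ for the world (the 5 sticks), $u$ for the revealed length, and
$w^* \in \{\text{longer}, \text{shorter}\}$ for the revealing contestant's
agenda.

**Literal listener** ($L_0$, the judge model `J0`): treats the revealed
stick as one of the world's five and updates the i.i.d.-uniform prior over
the remaining sticks by plain conditioning,

$$P_{L_0}(w \mid u) \propto \delta_{[\![u]\!]}(w)\,P(w).$$

Worlds whose mean is exactly 5 are excluded and the verdict probability
renormalized over {longer, shorter}: the slider's endpoints name a binary
proposition, and by symmetry this makes the prior belief exactly $1/2$.

**Motivated speaker**: chooses which of the five actual sticks to reveal by
a soft-max over a *persuasive utility*, the log-probability the literal
listener would assign to the agenda,

$$S(u \mid w, w^*, \beta) \propto \exp\big(\beta \ln L_0(w^* \mid u)\big),
\qquad u \in w .$$

Because only true sticks can be shown, the truthfulness (epistemic) part of
the utility is constant across the five choices and drops out. The
temperature of the soft-max and the persuasion weight enter only through
their product, so the package exposes a single bias parameter $\beta \ge 0$
(`speaker_params()`). The persuasive utility is strictly monotone in stick
length for each agenda, so as $\beta \to \infty$ the speaker shows the
single strongest stick; at $\beta = 0$ the choice is uniform over the five
sticks.

**Skeptical pragmatic listener** ($L_1$, the judge model `J1`): inverts the
speaker by exact enumeration,

$$P_{L_1}(w \mid u, w^*, \beta) \propto S(u \mid w, w^*, \beta)\, P(w),$$

marginalized to the verdict with the same tie handling. At $\beta = 0$ this
is exactly $L_0$; at large $\beta$, an 8-inch stick from a long-biased
contestant becomes *evidence against* "longer", because a strongly motivated
speaker holding a 9 would have shown it.

The **effect size** of a piece of supporting evidence is the prior belief in
the supported verdict minus the posterior: positive values mean backfire.

**Anchor-and-adjust baselines** (`aa_update()`): the asocial comparison
class shifts belief additively by the gap between the evidence's signed
strength $s(u)$ and a reference point $R$:
$P(w \mid u) = P(w) + \eta\,(s(u) - R)$, clipped to $[0, 1]$. The simple
variant fixes $\eta = 0.5, R = 0$; the minimum-acceptable-strength (MAS)
variant frees $R \in [-1, 1]$, letting weak positive evidence act as
negative evidence.

## Numerical choices in the exact models

* **State space.** Stick lengths are integers. All printed stick values are
  integers, and integer lengths make enumeration exact and the world space
  finite ($9^5 = 59{,}049$ ordered tuples). Computations run over the 1,287
  multisets with multiplicity weights; tests verify agreement with the
  ordered-tuple brute force to $10^{-10}$.
* **World prior.** I.i.d. uniform over lengths — the minimal assumption that
  delivers a prior verdict belief of exactly $1/2$ after tie exclusion.
* **Semantics of a revealed stick.** The revealed length is treated as one
  *revealed slot* plus four unconstrained sticks (equivalently, worlds are
  weighted by how many of their sticks match the utterance). This is forced
  by coherence: with the slot-based speaker, the pragmatic listener at
  $\beta = 0$ then reduces *exactly* to the literal listener rather than
  approximately.
* **Large $\beta$.** Speaker probabilities are computed in ratio form
  ($1/\sum_i c_i e^{\beta(\lambda_i-\lambda_u)}$), so $\beta = 10^6$ is
  numerically exact instead of overflowing.
* **The simulation figure's stick range.** The behavioral task uses lengths
  1–9, and that is the package default everywhere. The published
  bias-by-evidence simulation grid, however, spans evidence values up to
  10 inches, and its qualitative claims pin down the wider support: under
  lengths 1–10 (midpoint 5.5) an 8-inch stick backfires at $\beta = 100$
  (+0.201) while a 9-inch stick does not — exactly the figure's pattern —
  whereas under 1–9 the 8-inch stick never backfires (its limiting effect is
  $-0.01$). `cmd_simulate()` and the acceptance checks therefore reproduce
  the grid on `lengths = 1:10`; every experiment-facing computation stays on
  1–9. The `lengths` argument makes the choice explicit rather than hidden.

## Response model and the six variants

A participant's slider is modeled on the probability scale:
$y_i/100 \sim \mathcal N\big(\mathrm{clip}(p_i + o,\,0,\,1),\,\sigma\big)$,
where $p_i$ is the judge model's verdict belief, $o$ is a response offset
shared across participants (a global calibration of the slider scale), and
$\sigma$ is free response noise. A Gaussian on the probability scale is the
conventional slider likelihood; truncation at the bounds is deliberately not
modeled (a known, mild misspecification discussed below). Latent judge
assignments in mixture variants are marginalized analytically, never
sampled.

The six variants (`MODEL_VARIANTS`):

| variant | judge model(s) | free parameters |
|---|---|---|
| `aa_hom` | simple anchor-and-adjust | $o, \sigma$ |
| `mas_hom` | MAS | $\eta, R, o, \sigma$ |
| `mas_het` | AA/MAS mixture | $\eta, R, p_z, o, \sigma$ |
| `rsa_hom` | pragmatic `J1` | $\beta, o, \sigma$ |
| `rsa_het` | `J0`/`J1` mixture | $\beta, p_z, o, \sigma$ |
| `rsa_speaker` | `J0`/`J1`, per-group weights | $\beta, p_{z,1..5}, o, \sigma$ |

The speaker-dependent variant keys its five mixture weights by the
**agenda-relative priority rank** of the stick the participant said the
first contestant would show (rank 1 = that contestant's most persuasive
stick: 9 for long-biased, 2 for short-biased). Keying by raw stick identity
would conflate the two counterbalanced contestant orders — the "2" key would
pool short-biased strongest-expecters (pragmatic) with long-biased hedgers
(literal) — leaving no single parameter that means "the strongest-expected
group's weight". Relative ranks respect the counterbalancing and make the
headline contrast (strongest-expected weight near 1, others near 0) a
direct parameter readout.

For the baselines, evidence from the short-biased contestant is mirrored
through the midpoint before the update, so the anchor applies to
agenda-relative strength and one belief scale serves both orders; the
clipping (rather than a logistic link) keeps the additive rule exactly as
stated.

## Priors, fitting, and model comparison

Priors (the likelihood details of the original analysis are not in the main
text, so these are this package's own, documented choices):
$\beta \sim U(0, 10)$, $o \sim U(-0.5, 0.5)$,
$\sigma \sim \text{half-normal}(0.3)$, mixture weights and
$\eta \sim U(0, 1)$, and the MAS anchor $R \sim U(-1, 1)$ (the one prior the
source analysis states).

`run_mcmc()` uses componentwise adaptive random-walk Metropolis: each sweep
updates one parameter at a time with per-coordinate Gaussian proposals whose
scales adapt toward ~0.44 acceptance during burn-in only (adaptation then
freezes, preserving detailed balance for the kept draws). Componentwise
updates matter here: mixture weights for small sub-groups have broad, weakly
coupled posteriors that a joint random walk traverses far too slowly. The
default schedule mirrors the original analysis (1,000 kept draws over 4
chains, burn-in 7,500, thinning 100); split R-hat above 1.1 is reported as a
warning, not an error. The pragmatic-listener curve is cached by $\beta$
inside the likelihood closure, so the seven non-$\beta$ coordinate updates
of the speaker-dependent variant cost almost nothing.

`waic()` implements $-2(\mathrm{lppd} - p_{\text{WAIC}})$ with the
variance-based penalty; `psis_loo()` implements Pareto-smoothed importance
sampling with a generalized-Pareto fit (profile-posterior point estimate,
weakly regularized shape) to the top 20% of each observation's importance
ratios, truncation at the raw maximum, and per-observation $\hat k$
diagnostics (flags at 0.5/0.7). With degenerate (constant) draws both
criteria reduce exactly to $-2\,\mathrm{lppd}$, and tests check both against
exact leave-one-out refits of a conjugate normal model. `kfold_cv()`
provides seeded 10-fold MAP refits (the cross-validated
$\bar\beta, \bar o$ behind averaged belief curves).

`map_estimate()` is multi-start L-BFGS-B inside the prior box; the
model-comparison table's likelihood column reports the *maximized
log-likelihood* (`use_prior = FALSE`). The source table's "Likelihood"
column is on the log scale but is ambiguous between ML and MAP; with the
flat priors above the two essentially coincide.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the design: 723 participants (the
post-exclusion sample), contestant order counterbalanced exactly and shared
across phases, first evidence from {6,7,8,9} (long first) or {4,3,2,1}
(short first) with the weak condition oversampled (default strength weights
0.4/0.2/0.2/0.2), sliders on 0–100. Responder types are a latent mixture:
with probability `p_pragmatic` (default 0.67, the observed
strongest-expected share) a participant ranks sticks by persuasive utility
and answers with `J1` at `beta_true` (default 2.26, the reported MAP);
otherwise they hedge in the speaker phase and answer with `J0`.

Choices a scientist must make that the source leaves open:

* **Response noise.** `noise_sd = 0.18` (18 slider points), back-computed
  from the reported group confidence interval ([32.3, 37.3] around 34.7 for
  the oversampled weak cell of the strongest-expected group, roughly
  $485 \times 0.4$ participants). The response offset defaults to 0: the
  generator emulates model-faithful responders, and the fitted offset then
  has a known truth.
* **Hedging policy.** Literal responders' rank-1 stick is uniform over the
  four *non-strongest* candidates (`hedging = "weaker-first"`). The
  empirical hedging distribution is unreported, so any policy is a
  stand-in; this one is consistent with the observed 67/33
  strongest-vs-other split (a fully uniform ranking would inflate the
  strongest-expected share to ~74% by chance alone) and with the hedging
  group being *defined* by not picking the strongest stick first. The
  spec-style alternative (`"uniform"`) remains available as a config hook.
* **Second evidence.** Generated as a placeholder column, never modeled:
  order effects are out of scope.

Passing tests on these synthetics show the pipeline is *internally
coherent* — the fitting machinery recovers what the generator put in. They
cannot show that real participants obey a Gaussian slider likelihood, that
real hedgers rank uniformly among weaker sticks, or that real response
noise is homoscedastic; those claims need the study's actual data, which
the package can ingest through `read_participants()`.

A known edge of the emulation: generated sliders are clipped at 0/100 while
the likelihood is an unclipped Gaussian (truncation is an explicit
non-goal). Together with the boundary truth of the strongest group's weight
(exactly 1 by construction under `weaker-first` hedging), this makes the
point estimate of that weight sit slightly below 1 on typical realizations
(~0.85–1.0 across seeds at $n = 723$), while the generating $\beta$ stays
inside its 95% posterior interval and the speaker-dependent variant wins
the six-way comparison decisively.

## Problem sizes used by the tests and acceptance script

The default MCMC schedule above is the package's reference configuration;
the test suite and `scripts/acceptance.R` use a shorter, well-mixing
schedule chosen for routine re-runs: 1,000 kept draws over 4 chains,
burn-in 400 sweeps, thinning 3 (split R-hat ≈ 1.01 on the default dataset;
componentwise sweeps make this short schedule adequate). Recovery checks
run at the full study size $n = 723$; unit tests use smaller synthetic
tables (24–700 rows) and the full $9^5$ brute-force oracle.

## Limitations

* Single level of recursion; no listener uncertainty over $\beta$, no
  deception, no second-evidence order effects.
* The response likelihood family is a package choice (Gaussian,
  untruncated, shared $\sigma$); conclusions about variants that differ
  mainly in tail behavior should not be read off these fits.
* MAS anchoring is interpreted in the single-judgment sense (an implicit
  expectation from the cover story), the only reading available without
  multi-evidence trials.
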