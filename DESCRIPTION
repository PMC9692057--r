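Package: stickcontest
Title: Pragmatic Models of Persuasion and the Weak Evidence Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Exact Rational Speech Act (RSA) models of belief updating from a
    persuasive speaker on the Stick Contest state space, together with asocial
    anchor-and-adjust baselines, a synthetic-participant generator emulating the
    two-phase experimental design, and Bayesian model fitting with WAIC and
    PSIS-LOO model comparison across six model variants. The pragmatic listener
    inverts a soft-max speaker whose utility mixes truthfulness with a persuasion
    bias, which makes weak favourable evidence backfire when the speaker is
    expected to show the strongest evidence available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
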