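# Exact listener and speaker models, checked against independent brute-force
# enumeration oracles and frozen values computed from them.

test_that("literal listener matches brute-force completion enumeration", {
  expect_equal(literal_listener(5)[["longer"]], 0.5)       # symmetry
  expect_equal(literal_listener(9)[["longer"]], 0.789039767216, # oracle value
               tolerance = 1e-10)
  expect_equal(literal_listener(9)[["longer"]], oracle_literal(9),
               tolerance = 1e-12)
  for (u in c(2, 4, 6))
    expect_equal(literal_listener(u)[["longer"]], oracle_literal(u),
                 tolerance = 1e-12)
  # mirror symmetry of the uniform prior about the midpoint
  expect_equal(literal_listener(1)[["longer"]] +
                 literal_listener(9)[["longer"]], 1, tolerance = 1e-12)
  expect_equal(sum(literal_listener(7)), 1, tolerance = 1e-12)
})

test_that("persuasive utility is the log literal belief and is monotone", {
  expect_equal(persuasive_utility(5, "longer"), log(0.5))
  expect_equal(persuasive_utility(6, "longer"), -0.545288719874,
               tolerance = 1e-9)  # ln of the brute-force literal belief
  ul <- vapply(1:9, persuasive_utility, numeric(1), agenda = "longer")
  us <- vapply(1:9, persuasive_utility, numeric(1), agenda = "shorter")
  expect_true(all(diff(ul) > 0))   # strictly increasing toward "longer"
  expect_true(all(diff(us) < 0))   # strictly decreasing for "shorter"
})

test_that("speaker choice distribution interpolates uniform to argmax in beta", {
  w <- c(2, 4, 7, 8, 9)
  expect_equal(unname(speaker_distribution(w, "longer", speaker_params(0))),
               rep(0.2, 5))
  p_hi <- speaker_distribution(w, "longer", speaker_params(1e6))
  expect_gte(p_hi[["9"]], 1 - 1e-6)
  p_hi_s <- speaker_distribution(w, "shorter", speaker_params(1e6))
  expect_gte(p_hi_s[["2"]], 1 - 1e-6)
  # frozen oracle values at beta = 2 (L0^2 over the five sticks, normalized)
  expect_equal(unname(speaker_distribution(w, "longer", speaker_params(2))),
               c(0.0408485969955, 0.0964291787609, 0.23489321937,
                 0.288020253093, 0.339808751781), tolerance = 1e-9)
  # duplicated sticks pool their per-slot probability
  p_dup <- speaker_distribution(c(9, 9, 2, 4, 7), "longer", speaker_params(0))
  expect_equal(p_dup[["9"]], 0.4)
  expect_equal(sum(p_dup), 1)
})

test_that("pragmatic listener reduces to the literal listener at beta = 0", {
  for (u in 1:9)
    expect_equal(pragmatic_listener(u, "longer", speaker_params(0))[["longer"]],
                 literal_listener(u)[["longer"]], tolerance = 1e-10)
})

test_that("pragmatic listener agrees with the ordered-tuple oracle", {
  cases <- list(c(6, 2), c(6, 100), c(8, 100), c(7, 0.5), c(3, 10))
  for (cs in cases)
    expect_equal(
      pragmatic_listener(cs[1], "longer", speaker_params(cs[2]))[["longer"]],
      oracle_pragmatic(cs[1], "longer", cs[2]), tolerance = 1e-10)
  expect_equal(
    pragmatic_listener(6, "longer", speaker_params(100))[["longer"]],
    0.0278404890408, tolerance = 1e-9)  # frozen oracle value
  # skepticism: strong perceived bias discounts even an 8-inch stick below
  # its face value
  expect_lt(pragmatic_listener(8, "longer", speaker_params(100))[["longer"]],
            literal_listener(8)[["longer"]])
})

test_that("effect size is prior minus posterior with support checking", {
  p <- speaker_params(2)
  expect_equal(effect_size(6, "longer", p),
               0.5 - pragmatic_listener(6, "longer", p)[["longer"]])
  # no backfire without perceived bias
  for (u in 6:9)
    expect_lte(effect_size(u, "longer", speaker_params(0)), 0)
  expect_error(effect_size(4, "longer", p), "unsupported")
  expect_error(effect_size(5, "longer", p), "unsupported")
  expect_error(effect_size(7, "shorter", p), "unsupported")
})

test_that("effect sizes are mirror-symmetric across the two agendas", {
  for (b in c(0, 1, 2.26, 10, 100))
    for (u in 6:9)
      expect_equal(effect_size(u, "longer", speaker_params(b)),
                   effect_size(10 - u, "shorter", speaker_params(b)),
                   tolerance = 1e-10)
})

test_that("simulation grid is deterministic and matches frozen oracle values", {
  g1 <- simulation_grid(c(0, 1, 10, 100), 6:9)
  g2 <- simulation_grid(c(0, 1, 10, 100), 6:9)
  expect_identical(g1, g2)
  # frozen values from the ordered-tuple enumeration oracle
  oracle <- c(-0.0796743957, -0.1560196560, -0.2264289204, -0.2890397672,
              -0.0129294218, -0.0934481852, -0.1701454896, -0.2404409919,
               0.3136098452,  0.1285155566, -0.0618714417, -0.2053621781,
               0.4721595110,  0.2874037206, -0.0097258843, -0.2424036259)
  expect_equal(g1$effect_size, oracle, tolerance = 1e-8)
})

test_that("the set of backfiring evidence values is nondecreasing in bias", {
  for (lens in list(1:9, 1:10)) {
    utts <- intersect(6:max(lens), lens)  # evidence above either midpoint
    prev <- integer(0)
    for (b in c(0, 1, 10, 100)) {
      g <- simulation_grid(b, utts, lengths = lens)
      backfiring <- g$utterance[g$effect_size > 0]
      expect_true(all(prev %in% backfiring))
      prev <- backfiring
    }
  }
})
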