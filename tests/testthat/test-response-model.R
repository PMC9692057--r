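# Slider mapping, variant likelihoods, and the participant CSV round trip.

toy_records <- function() {
  data.frame(id = c("a", "b", "c"),
             first_contestant = c("longer", "shorter", "longer"),
             speaker_rank1 = c(9L, 2L, 4L),
             evidence1 = c(6L, 3L, 9L),
             slider1 = c(42, 30, 81))
}

test_that("predicted slider is the offset-shifted clipped belief", {
  expect_equal(predicted_slider(verdict_belief(0.5)), 50)
  expect_equal(predicted_slider(verdict_belief(0.5),
                                response_params(offset = -0.13)), 37)
  expect_equal(predicted_slider(verdict_belief(1),
                                response_params(offset = 0.2)), 100)
  # nondecreasing in belief and in offset
  ps <- vapply(seq(0, 1, 0.1), predicted_slider, numeric(1))
  expect_true(all(diff(ps) >= 0))
  po <- vapply(seq(-0.5, 0.5, 0.1), function(o)
    predicted_slider(0.4, response_params(offset = o)), numeric(1))
  expect_true(all(diff(po) >= 0))
})

test_that("speaker-phase choices map onto agenda-relative priority ranks", {
  expect_equal(speaker_choice_rank(9, "longer"), 1L)
  expect_equal(speaker_choice_rank(2, "shorter"), 1L)
  expect_equal(speaker_choice_rank(2, "longer"), 5L)
  expect_equal(speaker_choice_rank(c(7, 7), c("longer", "shorter")),
               c(3L, 3L))
})

test_that("variant likelihoods match hand-composed Gaussian densities", {
  rec <- toy_records()
  par <- list(beta = 2, weight = 0.6, offset = -0.05, noise_sd = 0.2)
  # hand-built oracle from the public listener models
  p1 <- c(pragmatic_listener(6, "longer", speaker_params(2))[["longer"]],
          pragmatic_listener(3, "shorter", speaker_params(2))[["longer"]],
          pragmatic_listener(9, "longer", speaker_params(2))[["longer"]])
  p0 <- vapply(rec$evidence1, function(u)
    literal_listener(u)[["longer"]], numeric(1))
  l1 <- dnorm(rec$slider1 / 100, pmin(pmax(p1 - 0.05, 0), 1), 0.2, log = TRUE)
  l0 <- dnorm(rec$slider1 / 100, pmin(pmax(p0 - 0.05, 0), 1), 0.2, log = TRUE)
  mix <- log(0.6 * exp(l1) + 0.4 * exp(l0))
  got <- dataset_loglik(rec, "rsa_het", par)
  expect_equal(got$pointwise, mix, tolerance = 1e-12)
  expect_equal(got$total, sum(mix), tolerance = 1e-12)
  # mixture log-likelihood lies between its component log-likelihoods
  expect_true(all(mix >= pmin(l1, l0) & mix <= pmax(l1, l0)))
})

test_that("mixture weights at the boundary reproduce the nested variants", {
  rec <- toy_records()
  base <- list(beta = 1.7, offset = 0.02, noise_sd = 0.15)
  hom <- dataset_loglik(rec, "rsa_hom", base)
  het1 <- dataset_loglik(rec, "rsa_het", c(base, weight = 1))
  expect_equal(het1$pointwise, hom$pointwise, tolerance = 1e-12)
  aa <- dataset_loglik(rec, "aa_hom", list(offset = 0, noise_sd = 0.15))
  mas0 <- dataset_loglik(rec, "mas_het",
                         list(eta = 0.8, anchor = 0.4, weight = 0,
                              offset = 0, noise_sd = 0.15))
  expect_equal(mas0$pointwise, aa$pointwise, tolerance = 1e-12)
  # a degenerate mixture with equal components is weight-invariant
  equal_mix <- vapply(c(0.1, 0.5, 0.9), function(w)
    dataset_loglik(rec, "mas_het",
                   list(eta = 0.5, anchor = 0, weight = w,
                        offset = 0, noise_sd = 0.15))$total, numeric(1))
  expect_equal(diff(range(equal_mix)), 0, tolerance = 1e-12)
})

test_that("speaker-dependent weights are selected by the participant's rank", {
  rec <- toy_records()   # ranks: 1 (9|longer), 1 (2|shorter), 4 (4|longer)
  par <- c(beta = 2, w_rank1 = 1, w_rank2 = 0.5, w_rank3 = 0.5, w_rank4 = 0,
           w_rank5 = 0.5, offset = 0, noise_sd = 0.2)
  got <- dataset_loglik(rec, "rsa_speaker", par)$pointwise
  hom <- dataset_loglik(rec, "rsa_hom",
                        c(beta = 2, offset = 0, noise_sd = 0.2))$pointwise
  expect_equal(got[1:2], hom[1:2], tolerance = 1e-12)   # weight 1 -> pure J1
  p0 <- literal_listener(9)[["longer"]]
  expect_equal(got[3], dnorm(0.81, p0, 0.2, log = TRUE), tolerance = 1e-12)
})

test_that("dataset log-likelihood is additive and order-stable", {
  rec <- toy_records()
  par <- list(beta = 2, offset = 0, noise_sd = 0.2)
  one <- dataset_loglik(rec[1, ], "rsa_hom", par)
  expect_length(one$pointwise, 1L)
  expect_equal(one$total, one$pointwise)
  both <- dataset_loglik(rec, "rsa_hom", par)
  expect_equal(both$total, sum(vapply(1:3, function(i)
    participant_loglik(rec[i, ], "rsa_hom", par), numeric(1))))
  expect_error(dataset_loglik(rec, "rsa_mystery", par), "unknown variant")
  expect_error(dataset_loglik(rec, "rsa_het", par), "missing parameter")
  expect_error(dataset_loglik(rec[0, ], "rsa_hom", par), "empty")
})

test_that("participant tables survive a CSV round trip with derived groups", {
  d <- generate_dataset(generator_config(n_participants = 40, seed = 5))
  f <- tempfile(fileext = ".csv")
  write_participants(d, f)
  back <- read_participants(f)
  cols <- c("id", "first_contestant", "speaker_rank1", "evidence1", "group")
  expect_equal(back[cols], d[cols])
  expect_equal(back$slider1, d$slider1, tolerance = 1e-9)
  expect_equal(names(utils::read.csv(f)),
               c("id", "first_contestant", "speaker_rank1", "evidence1",
                 "slider1"))
})

test_that("validation reports offending rows and can drop them", {
  bad <- toy_records()
  bad$evidence1[2] <- 7L            # shorter-first must show 1..4
  bad$slider1[3] <- 130             # out of slider range
  expect_error(validate_participants(bad), "row\\(s\\): 2, 3")
  expect_warning(ok <- validate_participants(bad, reject = "drop"),
                 "row\\(s\\): 2, 3")
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$group, "strongest-expected")
  expect_error(validate_participants(bad[, -3]), "missing column")
})
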