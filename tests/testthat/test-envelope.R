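make_binary_mix <- function() {
  mixture(tibble::tibble(id = c("A", "B"), a = c(1, 1),
                         c = c(1e-9, 4e-9), n = c(1, 1)),
          fractions = c(0.5, 0.5))
}

test_that("degenerate (zero-width) uncertainty collapses the envelope", {
  mix <- make_binary_mix()
  des <- mixture_design(mix)
  unc <- uncertainty_uniform(mix, rel = 0)   # point-mass distributions
  env <- mc_envelope(des, unc, "GRA", n_sims = 1000, seed = 1)
  det <- predict_curve_gra(des)
  expect_equal(env$band$lower, det$response, tolerance = 1e-12)
  expect_equal(env$band$median, det$response, tolerance = 1e-12)
  expect_equal(env$band$upper, det$response, tolerance = 1e-12)
})

test_that("envelope width grows with parameter uncertainty", {
  mix <- make_binary_mix()
  des <- mixture_design(mix)
  widths <- sapply(c(0.05, 0.15, 0.3), function(rel) {
    env <- mc_envelope(des, uncertainty_uniform(mix, rel), "GRA",
                       n_sims = 2000, seed = 7)
    mean(env$band$upper - env$band$lower)
  })
  expect_true(all(diff(widths) > 0))
})

test_that("envelopes are bit-reproducible for a fixed seed", {
  mix <- make_binary_mix()
  des <- mixture_design(mix)
  unc <- uncertainty_uniform(mix, 0.1)
  e1 <- mc_envelope(des, unc, "GRA", n_sims = 1000, seed = 42)
  e2 <- mc_envelope(des, unc, "GRA", n_sims = 1000, seed = 42)
  expect_identical(e1$band, e2$band)
  e3 <- mc_envelope(des, unc, "CA", n_sims = 1000, seed = 42)
  e4 <- mc_envelope(des, unc, "CA", n_sims = 1000, seed = 42)
  expect_identical(e3$band, e4$band)
  expect_true(all(e1$band$lower <= e1$band$median),
              all(e1$band$median <= e1$band$upper))
})

test_that("inconsistent uncertainty specifications are refused", {
  mix <- make_binary_mix()
  des <- mixture_design(mix)
  bad <- uncertainty_uniform(mix, 0.1)
  bad$dist <- "normal"
  bad$p1[bad$param == "a"] <- -5   # nearly all efficacy draws invalid
  bad$p2[bad$param == "a"] <- 0.5
  expect_error(mc_envelope(des, bad, "GRA", n_sims = 1000, seed = 1),
               "invalid")
  expect_error(mc_envelope(des, uncertainty_uniform(mix, 0.1), "GRA",
                           n_sims = 100, seed = 1), ">= 1000")
})

test_that("an observed curve equal to the median is declared additive", {
  mix <- make_binary_mix()
  des <- mixture_design(mix)
  env <- mc_envelope(des, uncertainty_uniform(mix, 0.1), "GRA",
                     n_sims = 1000, seed = 3)
  obs <- tibble::tibble(concentration = env$band$concentration,
                        response = env$band$median)
  v <- additivity_test(obs, env)
  expect_identical(v$overall, "additive")
  expect_true(all(tidy(v)$flag == "inside"))
})

test_that("model-consistent noisy data are usually judged additive", {
  mix <- make_binary_mix()
  des <- mixture_design(mix)
  unc <- uncertainty_uniform(mix, 0.1)
  verdicts <- sapply(1:30, function(s) {
    env <- mc_envelope(des, unc, "GRA", n_sims = 1000, seed = 1000 + s)
    d <- simulate_curve(mix, seed = 2000 + s)
    additivity_test(tibble::tibble(concentration = d$concentration_M,
                                   response = d$response_pct), env)$overall
  })
  expect_gte(mean(verdicts == "additive"), 0.9)
})

test_that("a genuine potency shift is detected as synergy", {
  mix <- make_binary_mix()
  des <- mixture_design(mix)
  unc <- uncertainty_uniform(mix, 0.1)
  shifted <- mixture(dplyr::mutate(mix[, c("id", "a", "c", "n")], c = c / 2),
                     fractions = mix$fraction)   # true EC50 halved
  verdicts <- sapply(1:20, function(s) {
    env <- mc_envelope(des, unc, "GRA", n_sims = 1000, seed = 1000 + s)
    d <- simulate_curve(shifted, seed = 3000 + s)
    additivity_test(tibble::tibble(concentration = d$concentration_M,
                                   response = d$response_pct), env)$overall
  })
  expect_gt(mean(verdicts == "synergy_candidate"), 0.5)
})

test_that("the verdict ignores padding at baseline concentrations", {
  mix <- make_binary_mix()
  grid <- ca_mixture_ecx(mix, 50) * 10^seq(-2, 2, length.out = 8)
  padded <- c(grid[1] * c(1e-4, 1e-3), grid)
  des <- mixture_design(mix, grid = grid)
  des_p <- mixture_design(mix, grid = padded)
  unc <- uncertainty_uniform(mix, 0.1)
  env <- mc_envelope(des, unc, "GRA", n_sims = 1000, seed = 5)
  env_p <- mc_envelope(des_p, unc, "GRA", n_sims = 1000, seed = 5)
  d <- simulate_curve(mix, seed = 77)
  obs <- tibble::tibble(concentration = d$concentration_M,
                        response = d$response_pct)
  obs_p <- dplyr::bind_rows(
    tibble::tibble(concentration = padded[1:2], response = 0), obs)
  expect_identical(additivity_test(obs, env)$overall,
                   additivity_test(obs_p, env_p)$overall)
})

test_that("compare_models scores both models and names the winner", {
  mix <- make_binary_mix()
  des <- mixture_design(mix)
  gra <- predict_curve_gra(des)
  ca <- predict_curve_ca(des)
  obs <- tibble::tibble(concentration = gra$concentration,
                        response = gra$response)
  cmp <- compare_models(obs, ca, gra)
  expect_equal(cmp$rmse[cmp$model == "GRA"], 0, tolerance = 1e-12)
  # unit efficacy and slope: CA and GRA coincide, reported as a tie
  expect_identical(attr(cmp, "winner"), "tie")

  # supra-agonist mixture: GRA should beat CA on data it generated
  supra <- mixture(tibble::tibble(id = c("S", "F"), a = c(1.9, 1),
                                  c = c(1e-9, 4e-9), n = c(1.4, 1)),
                   fractions = c(0.5, 0.5))
  des2 <- mixture_design(supra)
  gra2 <- predict_curve_gra(des2)
  ca2 <- suppressWarnings(predict_curve_ca(des2))
  wins <- sapply(1:20, function(s) {
    d <- simulate_curve(supra, plate_design(top = max(des2$grid), step = 10^(4 / 7)),
                        seed = 6000 + s)
    obs2 <- tibble::tibble(concentration = d$concentration_M,
                           response = d$response_pct)
    attr(compare_models(obs2, ca2, gra2), "winner")
  })
  expect_gt(mean(wins == "GRA"), 0.5)
})
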