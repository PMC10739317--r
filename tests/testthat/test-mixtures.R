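test_that("equipotent fractions are proportional to each component's ECx", {
  eq <- equipotent_fractions(
    data.frame(id = c("A", "B"), a = c(1, 1), c = c(1e-9, 1e-9), n = c(1, 1)),
    X = 50)
  expect_equal(eq$fraction, c(0.5, 0.5))
  # ECx ratio 1:9 puts 90% of the blend on the weak component
  eq2 <- equipotent_fractions(
    data.frame(id = c("A", "B"), a = c(1, 1), c = c(1e-9, 9e-9), n = c(1, 1)),
    X = 50)
  expect_equal(eq2$fraction, c(0.1, 0.9))
  for (seed in 1:5) {
    lig <- rand_ligands(3, seed, a_range = c(0.8, 2))
    expect_equal(sum(equipotent_fractions(lig, 10)$fraction), 1)
  }
  expect_error(equipotent_fractions(
    data.frame(a = c(1, 0.4), c = c(1e-9, 1e-9), n = c(1, 1)), X = 50),
    "Unreachable")
})

test_that("a blend of identical full agonists is indistinguishable from one", {
  one <- ligand(1, 1e-9, 1, id = "A")
  blend <- mixture(tibble::tibble(id = c("A1", "A2"), a = 1,
                                  c = 1e-9, n = 1), fractions = c(0.5, 0.5))
  grid <- 1e-9 * 10^seq(-2, 2, length.out = 9)
  des <- mixture_design(blend, grid = grid)
  pred <- predict_curve_gra(des)
  expect_equal(pred$response, hill_response(one, grid), tolerance = 1e-12)
})

test_that("CA prediction equals GRA for unit-efficacy unit-slope mixtures", {
  for (seed in 1:8) {
    k <- 2 + seed %% 3
    mix <- rand_mixture(k, 100 + seed, a_range = c(1, 1), n_range = c(1, 1))
    des <- mixture_design(mix)
    ca <- predict_curve_ca(des)
    gra <- predict_curve_gra(des)
    expect_equal(ca$response, gra$response, tolerance = 1e-6)
  }
})

test_that("single-component CA collapses to the component's Hill curve", {
  lig <- ligand(1, 2e-8, 1.3, id = "solo")
  des <- mixture_design(mixture(lig, fractions = 1))
  ca <- predict_curve_ca(des)
  expect_equal(ca$response, hill_response(lig, des$grid), tolerance = 1e-8)
})

test_that("the CA mixture EC50 is read off the predicted curve", {
  mix <- mixture(data.frame(a = c(1, 1), c = c(1e-6, 3e-6), n = c(1, 1)),
                 fractions = c(0.5, 0.5))
  grid <- 10^seq(-8, -4, length.out = 25)
  ca <- predict_curve_ca(mixture_design(mix, grid = grid))
  # root-find the 50% crossing of the predicted curve
  f <- stats::approxfun(log(ca$concentration), ca$response - 50)
  ec50 <- exp(stats::uniroot(f, range(log(ca$concentration)))$root)
  expect_equal(ec50, 1.5e-6, tolerance = 1e-3)
  expect_equal(ca_mixture_ecx(mix, 50), 1.5e-6)
})

test_that("partial agonists truncate the CA curve with an explicit record", {
  mix <- mixture(data.frame(id = c("full", "part"), a = c(1, 0.6),
                            c = c(1e-7, 1e-7), n = c(1, 1)),
                 fractions = c(0.5, 0.5))
  grid <- 10^seq(-9, -3, length.out = 12)
  expect_warning(ca <- predict_curve_ca(mixture_design(mix, grid = grid)),
                 "truncated")
  tr <- attr(ca, "truncation")
  expect_identical(tr$limiting, "part")
  expect_equal(tr$ceiling_pct, 60)
  expect_gt(tr$n_capped, 0)
  # the whole curve, capped tail included, respects the ceiling
  expect_true(all(ca$response <= 60 + 1e-9))
  expect_equal(max(ca$response), 60, tolerance = 1e-9)
})

test_that("predicted curves are monotone and order-invariant", {
  # equal-efficacy agonist mixtures: both models are non-decreasing in the
  # total concentration (mixed efficacies can legitimately produce a
  # non-monotone GRA curve, as receptor competition lets a steep weak
  # component pull the response toward its own ceiling)
  for (seed in 11:15) {
    a_common <- withr::with_seed(seed, stats::runif(1, 0.5, 2))
    mix <- rand_mixture(3, seed, a_range = c(a_common, a_common))
    des <- mixture_design(mix)
    gra <- predict_curve_gra(des)
    expect_true(all(diff(gra$response) >= -1e-9))
    ca <- suppressWarnings(predict_curve_ca(des))
    expect_true(all(diff(ca$response) >= -1e-9, na.rm = TRUE))
    perm <- mixture(mix[c(3, 1, 2), c("id", "a", "c", "n")],
                    fractions = mix$fraction[c(3, 1, 2)])
    gra_p <- predict_curve_gra(mixture_design(perm, grid = des$grid))
    expect_equal(gra_p$response, gra$response, tolerance = 1e-12)
  }
})

test_that("components below their individual LoD jointly exceed it", {
  # k identical full agonists, each dosed below its own 10%-effect
  # concentration, together produce a measurable (>10%) joint effect
  lig1 <- ligand(1, 1e-9, 1)
  ec10 <- ecx_from_hill(lig1, 10)
  for (k in 2:5) {
    blend <- mixture(tibble::tibble(id = paste0("A", 1:k), a = 1,
                                    c = 1e-9, n = 1),
                     fractions = rep(1 / k, k))
    dose_each <- ec10 * 0.9          # strictly below the individual LoD
    expect_lt(hill_response(lig1, dose_each), 10)
    joint <- gra_response(blend[, c("id", "a", "c", "n")],
                          rep(dose_each, k))
    expect_gt(joint, 10)
  }
})

test_that("co-exposure designs hold the reference dose fixed", {
  e2 <- ligand(1, 5e-12, 1, id = "E2")
  mix <- mixture(tibble::tibble(id = c("dai", "kae"), a = c(1.9, 0.6),
                                c = c(4e-7, 2e-6), n = c(1.3, 1)),
                 fractions = c(0.5, 0.5))
  grid <- 10^seq(-12, -4, length.out = 15)
  des <- mixture_design(mix, "coexposure_with_reference", grid = grid,
                        reference = e2)
  pred <- predict_curve_gra(des)
  # highly diluted mixture: the reference response at its EC50 (50%) stands
  expect_equal(pred$response[1], 50, tolerance = 0.5)
  # saturating supra-agonist mixture strengthens the response well past 50%
  expect_gt(dplyr::last(pred$response), 100)
  expect_error(predict_curve_ca(des), "co-exposure")
})
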