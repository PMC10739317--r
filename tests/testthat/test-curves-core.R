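test_that("hill_response obeys baseline, midpoint and plateau limits", {
  sc <- reference_scale()
  full <- ligand(a = 1, c = 1e-9, n = 1)
  expect_identical(hill_response(full, 0), 0)
  expect_equal(hill_response(full, 1e-9), 50)
  # partial agonist approaches its own ceiling, 60% of the reference span
  partial <- ligand(a = 0.6, c = 1e-9, n = 1)
  expect_equal(hill_response(partial, 1e-9 * 1e6), 60, tolerance = 1e-5)
  # shifted scale
  sc2 <- reference_scale(y0 = 5, m = 105)
  expect_identical(hill_response(full, 0, sc2), 5)
  expect_equal(hill_response(full, 1e-9, sc2), 55)
})

test_that("hill_response rejects invalid doses and parameters", {
  lig <- ligand(1, 1e-9, 1)
  expect_error(hill_response(lig, -1), "finite and >= 0")
  expect_error(hill_response(lig, NaN), "finite")
  expect_error(ligand(1, -1e-9, 1), "Potency")
  expect_error(ligand(-0.1, 1e-9, 1), "Efficacy")
  expect_error(ligand(1, 1e-9, 0), "slope")
})

test_that("single-ligand GRA reduces exactly to the Hill curve", {
  for (seed in 1:20) {
    lig <- rand_ligands(1, seed)
    x <- withr::with_seed(seed + 100L, 10^stats::runif(6, -12, -4))
    expect_identical(gra_response(lig, matrix(x, nrow = 1)),
                     hill_response(lig, x))
  }
})

test_that("a pure antagonist occupies receptor without activating it", {
  lig <- data.frame(id = c("ag", "ant"), a = c(1, 0), c = c(1, 1), n = c(1, 1))
  expect_equal(gra_response(lig, c(1, 9)), 100 / 11)
  # agonist alone at its EC50 gives 50; any antagonist strictly lowers it
  expect_equal(gra_response(lig, c(1, 0)), 50)
  for (x_ant in c(0.1, 1, 10)) {
    expect_lt(gra_response(lig, c(1, x_ant)), 50)
  }
})

test_that("gra_response stays within the efficacy-bounded band", {
  for (seed in 21:30) {
    lig <- rand_ligands(3, seed)
    doses <- withr::with_seed(seed, matrix(10^stats::runif(15, -12, -3), nrow = 3))
    y <- gra_response(lig, doses)
    expect_true(all(y >= 0 - 1e-12))
    expect_true(all(y <= 100 * max(lig$a) + 1e-9))
  }
})

test_that("gra_response is stable at saturating doses", {
  lig <- ligand(a = 1.5, c = 1e-9, n = 3)
  expect_equal(gra_response(lig, matrix(1e2, 1, 1)), 150)
})

test_that("ecx_from_hill matches its closed form and names offenders", {
  expect_equal(ecx_from_hill(ligand(1, 1e-8, 1), 50), 1e-8)
  # r/(a - r) = 1 when a = 0.6, X = 30: the ECx is just c
  expect_equal(ecx_from_hill(ligand(0.6, 2e-6, 1), 30), 2e-6)
  expect_error(ecx_from_hill(ligand(0.6, 2e-6, 1, id = "kae"), 70),
               "Unreachable.*kae")
  expect_error(ecx_from_hill(ligand(1, 1e-8, 1), 0), "positive")
})

test_that("ecx and hill_response are mutual inverses on the reachable range", {
  for (seed in 31:45) {
    lig <- rand_ligands(1, seed)
    X <- withr::with_seed(seed, stats::runif(1, 1, 99) * lig$a * 0.98)
    x <- ecx_from_hill(lig, X)
    expect_equal(hill_response(lig, x), 100 * X / 100, tolerance = 1e-9)
    # forward evaluation then re-inversion
    y <- hill_response(lig, x)
    expect_equal(ecx_from_hill(lig, y), x, tolerance = 1e-9)
  }
})

test_that("ca_mixture_ecx follows the harmonic fraction-weighted form", {
  one <- mixture(data.frame(a = 1, c = 2e-6, n = 1), fractions = 1)
  expect_equal(ca_mixture_ecx(one, 50), 2e-6)
  two <- mixture(data.frame(a = c(1, 1), c = c(1e-6, 3e-6), n = c(1, 1)),
                 fractions = c(0.5, 0.5))
  expect_equal(ca_mixture_ecx(two, 50), 1.5e-6)
  same <- mixture(data.frame(a = c(1, 1), c = c(2e-6, 2e-6), n = c(1, 1)),
                  fractions = c(0.5, 0.5))
  expect_equal(ca_mixture_ecx(same, 50), 2e-6)
  # partial agonists block high effect levels, and the error says who
  mixed <- mixture(data.frame(id = c("full", "part"), a = c(1, 0.6),
                              c = c(1e-6, 1e-6), n = c(1, 1)),
                   fractions = c(0.5, 0.5))
  expect_error(ca_mixture_ecx(mixed, 70), "part")
})

test_that("mixture() enforces fraction invariants", {
  lig <- data.frame(a = c(1, 1), c = c(1e-9, 1e-9), n = c(1, 1))
  expect_error(mixture(lig, c(0.5, 0.6)), "sum to 1")
  expect_error(mixture(lig, c(1.1, -0.1)), ">= 0")
  expect_error(mixture(lig, 1), "one fraction per component")
})

test_that("apparent EC50 shift matches the Schild closed form", {
  ag <- ligand(1, 1e-9, 1, id = "ag")
  ant <- ligand(0, 1e-8, 1, id = "ant")
  expect_identical(apparent_ec50_shift(ag, ant, 0), 1e-9)
  expect_equal(apparent_ec50_shift(ag, ant, 9e-8), 10e-9, tolerance = 1e-6)
  # generic closed form c_ag (1 + x/c_ant) at several antagonist doses,
  # and a strictly larger shift when the dose doubles
  prev <- 0
  for (x_ant in c(1e-9, 5e-8, 2e-7)) {
    got <- apparent_ec50_shift(ag, ant, x_ant)
    expect_equal(got, 1e-9 * (1 + x_ant / 1e-8), tolerance = 1e-6)
    expect_gt(got, prev)
    prev <- got
  }
  expect_gt(apparent_ec50_shift(ag, ant, 4e-7),
            apparent_ec50_shift(ag, ant, 2e-7))
  expect_error(apparent_ec50_shift(ag, ligand(0.2, 1e-8, 1), 1e-8),
               "a = 0")
})

test_that("antagonist IC50 matches competitive-occupancy algebra", {
  ag <- ligand(1, 1e-9, 1, id = "ag")
  ant <- ligand(0, 1e-8, 1, id = "ant")
  # at x_ag = c_ag the occupancy model gives IC50 = 2 c_ant
  ic <- ic50_of_antagonist(ag, 1e-9, ant)
  expect_equal(ic, 2e-8, tolerance = 1e-6)
  # doubling the antagonist pushes the response below half
  pair <- dplyr::bind_rows(ag, ant)
  half <- 50 / 2
  expect_lt(gra_response(pair, c(1e-9, 2 * ic)), half)
  # invariant to affine rescaling of the response axis
  sc <- reference_scale(y0 = 7, m = 180)
  expect_equal(ic50_of_antagonist(ag, 1e-9, ant, sc), ic, tolerance = 1e-8)
})
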