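# Shared fixtures: random but seeded parameter draws and a shortcut from
# the plate dialect to fit_hill()'s column names.

rand_ligands <- function(k, seed, a_range = c(0.5, 2), n_range = c(0.5, 5),
                         lc_range = c(-11, -5)) {
  withr::with_seed(seed, tibble::tibble(
    id = paste0("L", seq_len(k)),
    a = stats::runif(k, a_range[1], a_range[2]),
    c = 10^stats::runif(k, lc_range[1], lc_range[2]),
    n = stats::runif(k, n_range[1], n_range[2])))
}

rand_mixture <- function(k, seed, ...) {
  lig <- rand_ligands(k, seed, ...)
  f <- withr::with_seed(seed + 1L, stats::runif(k))
  mixture(lig, fractions = f / sum(f))
}

as_fit_data <- function(plate) {
  dplyr::tibble(concentration = plate$concentration_M,
                response = plate$response_pct)
}

# Simulate, fit and score one equipotent binary mixture of identical full
# agonists under multiplicative noise: the goodness of fit is evaluated
# between the fitted curve and the measured (replicate-mean) curve.
noise_sim_gof <- function(seed, noise = 0.07, ec50 = 1e-9) {
  mix <- mixture(tibble::tibble(id = c("A1", "A2"), a = c(1, 1),
                                c = c(ec50, ec50), n = c(1, 1)),
                 fractions = c(0.5, 0.5))
  grid <- ec50 * 10^seq(-2, 2, length.out = 8)
  doses <- outer(mix$fraction, grid)
  y_true <- gra_response(mix[, c("id", "a", "c", "n")], doses)
  obs <- withr::with_seed(seed, {
    y <- rep(y_true, each = 3)
    pmax(0, y + stats::rnorm(length(y), 0, noise * y))
  })
  dat <- tibble::tibble(concentration = rep(grid, each = 3), response = obs)
  fit <- fit_gra(dat, mix, share_params = TRUE)
  mean_obs <- tapply(dat$response, dat$concentration, mean)
  pred <- gra_response(fit$params[, c("a", "c", "n")],
                       outer(fit$params$fraction, grid))
  cbind(goodness_of_fit(as.numeric(mean_obs), pred),
        converged = fit$converged)
}
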