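#' @importFrom rlang .data
NULL

# ---- internal Levenberg-Marquardt machinery -------------------------------
#
# All curve fits share one engine: minpack.lm::nls.lm on a residual
# function, with the EC50 handled internally as log10(c) (the raw (a, c, n)
# parameterisation makes the normal equations numerically singular at
# picomolar potencies). Standard errors come from a heteroscedasticity-
# robust (HC3-type) sandwich around the Jacobian: luminescence noise is
# multiplicative, so the classical constant-variance covariance badly
# understates the uncertainty of plateau-driven parameters.

lm_engine <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- fit$deviance
    if (is.null(best) || ss < best$deviance - 1e-12 ||
        (abs(ss - best$deviance) <= 1e-12 && mean_slope(fit$par) < mean_slope(best$par))) {
      best <- fit
    }
  }
  best
}

mean_slope <- function(par) mean(par[grepl("^n", names(par))])

num_jacobian <- function(fn, par) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par),
              dimnames = list(NULL, names(par)))
  for (j in seq_along(par)) {
    h <- max(abs(par[j]), 1e-4) * 1e-6
    pp <- pm <- par
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

robust_vcov <- function(J, r) {
  n <- length(r); p <- ncol(J)
  JtJi <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  if (is.null(JtJi)) return(NULL)
  lev <- pmin(rowSums((J %*% JtJi) * J), 0.9999)
  w <- r / (1 - lev)                       # HC3 leverage correction
  meat <- crossprod(J * w)
  list(vcov = JtJi %*% meat %*% JtJi, df = n - p)
}

new_hill_fit <- function(params, scale, rmse, rsq, n_obs, converged,
                         residuals, fitted, data, vcov, df, note = NULL,
                         kind = "hill") {
  structure(
    list(params = params, scale = scale, rmse = rmse, rsq = rsq,
         n_obs = n_obs, converged = converged, residuals = residuals,
         fitted = fitted, data = data, vcov = vcov, df = df, note = note,
         kind = kind),
    class = "hill_fit")
}

default_hill_init <- function(conc, resp, scale) {
  yb <- tapply(resp, conc, mean)
  xs <- as.numeric(names(yb))
  amax <- max(yb) - scale$y0
  a0 <- max(amax / span(scale), 0.05)
  half <- scale$y0 + amax / 2
  c0 <- xs[which.min(abs(yb - half))]
  c(a = a0, lc = log10(c0), n = 1)
}

# Deterministic multi-start: the plain initialiser plus five log-spaced
# shifts of the potency. Best sum of squares wins; ties go to the shallower
# slope.
starts_around <- function(init) {
  shifts <- seq(-2, 2, length.out = 5)
  c(list(init),
    lapply(shifts, function(s) { st <- init; st["lc"] <- st["lc"] + s; st }))
}

#' Fit a Hill curve to concentration-response data
#'
#' Estimates efficacy `a`, potency `c` (EC50) and Hill slope `n` of a
#' single compound by unweighted least squares, minimised with the
#' Levenberg-Marquardt algorithm. The reference scale `(y0, m)` is fixed
#' (it comes from the plate's reference-agonist fit, see
#' [fit_e2_reference()]). The potency is optimised as `log10(c)`;
#' standard errors use a heteroscedasticity-robust sandwich covariance and
#' are reported on the natural scale by the delta method.
#'
#' Starting values default to `a = ` max mean response / span, `c = `
#' the concentration nearest half-max, `n = 1`, refined over a fixed set
#' of log-spaced potency perturbations; the fit is deterministic.
#' Bounds: `a` in \[0, 3\], `n` in \[0.1, 10\], `c` within the tested
#' concentration range widened 100-fold either side.
#'
#' @param data Data frame with columns `concentration` (molar, > 0) and
#'   `response` (percent activity); replicates are extra rows.
#' @param scale A [reference_scale()].
#' @param init Optional named vector / list with starting `a`, `c`, `n`.
#' @param fix Optional named list of parameters to hold fixed, e.g.
#'   `list(a = 1)`.
#' @return A `hill_fit` object; see [tidy.hill_fit()], [glance.hill_fit()],
#'   [autoplot.hill_fit()]. `converged` is `FALSE` (with a `note`) for
#'   degenerate inputs such as a constant response.
#' @examples
#' lig <- ligand(a = 1.8, c = 1e-9, n = 2)
#' d <- simulate_curve(lig, noise_fraction = 0, seed = 1)
#' fit <- fit_hill(dplyr::rename(d, concentration = concentration_M,
#'                               response = response_pct))
#' tidy(fit)
#' @export
fit_hill <- function(data, scale = reference_scale(), init = NULL, fix = NULL) {
  dat <- check_fit_data(data)
  conc <- dat$concentration; resp <- dat$response

  if (stats::sd(resp) == 0) {
    return(new_hill_fit(
      params = tibble::tibble(id = "fit", a = NA_real_, c = NA_real_,
                              n = NA_real_),
      scale = scale, rmse = NA_real_, rsq = NA_real_, n_obs = length(resp),
      converged = FALSE, residuals = rep(NA_real_, length(resp)),
      fitted = rep(NA_real_, length(resp)), data = dat, vcov = NULL,
      df = NA_integer_, note = "degenerate input: constant response"))
  }

  init0 <- default_hill_init(conc, resp, scale)
  if (!is.null(init)) {
    init <- as.list(init)
    if (!is.null(init$a)) init0["a"] <- init$a
    if (!is.null(init$c)) init0["lc"] <- log10(init$c)
    if (!is.null(init$n)) init0["n"] <- init$n
  }
  lower <- c(a = 0, lc = log10(min(conc)) - 2, n = 0.1)
  upper <- c(a = 3, lc = log10(max(conc)) + 2, n = 10)

  fixed <- unlist(fix)
  if (!is.null(fixed) && "c" %in% names(fixed)) {
    fixed <- c(fixed[setdiff(names(fixed), "c")], lc = log10(fixed[["c"]]))
  }
  free <- setdiff(names(init0), names(fixed))

  model_fn <- function(par) {
    full <- c(par, fixed)[c("a", "lc", "n")]
    hill_pred(full["a"], full["lc"], full["n"], conc, scale)
  }
  resid_fn <- function(par) resp - model_fn(par)

  starts <- lapply(starts_around(init0), function(s) s[free])
  fit <- lm_engine(resid_fn, starts, lower[free], upper[free])
  finish_fit(fit, model_fn, resid_fn, free, fixed, conc, resp, scale, dat,
             id = "fit")
}

hill_pred <- function(a, lc, n, x, scale) {
  u <- exp(n * (log(x) - log(10^lc)))
  frac <- ifelse(is.infinite(u), 1, u / (1 + u))
  scale$y0 + span(scale) * a * frac
}

check_fit_data <- function(data) {
  if (!is.data.frame(data)) stop("`data` must be a data frame.", call. = FALSE)
  need <- setdiff(c("concentration", "response"), names(data))
  if (length(need)) {
    stop("`data` is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dat <- tibble::as_tibble(data)[c("concentration", "response")]
  if (any(!is.finite(dat$concentration)) || any(dat$concentration <= 0)) {
    stop("Concentrations must be finite and > 0.", call. = FALSE)
  }
  if (any(!is.finite(dat$response))) {
    stop("Responses must be finite.", call. = FALSE)
  }
  if (length(unique(dat$concentration)) < 4L) {
    stop("Need at least 4 distinct concentrations to fit a sigmoid.",
         call. = FALSE)
  }
  dat
}

finish_fit <- function(fit, model_fn, resid_fn, free, fixed, conc, resp,
                       scale, dat, id) {
  n_obs <- length(resp)
  if (is.null(fit)) {
    return(new_hill_fit(
      params = tibble::tibble(id = id, a = NA_real_, c = NA_real_, n = NA_real_),
      scale = scale, rmse = NA_real_, rsq = NA_real_, n_obs = n_obs,
      converged = FALSE, residuals = rep(NA_real_, n_obs),
      fitted = rep(NA_real_, n_obs), data = dat, vcov = NULL,
      df = NA_integer_, note = "Levenberg-Marquardt did not converge"))
  }
  par <- fit$par
  full <- c(par, fixed)[c("a", "lc", "n")]
  fitted <- model_fn(par)
  r <- resp - fitted
  gof <- goodness_of_fit(resp, fitted)
  J <- num_jacobian(function(p) -resid_fn(p), par)
  rob <- robust_vcov(J, r)
  converged <- fit$info %in% 1:4 && !is.null(rob)

  se <- rep(NA_real_, length(par)); names(se) <- names(par)
  if (!is.null(rob)) se <- sqrt(pmax(diag(rob$vcov), 0))
  se_full <- c(a = NA_real_, lc = NA_real_, n = NA_real_)
  se_full[names(se)] <- se
  if (!is.null(fixed)) se_full[names(fixed)] <- 0
  names(se_full)[names(se_full) == "lc"] <- "lc"

  params <- tibble::tibble(
    id = id,
    a = unname(full["a"]), c = 10^unname(full["lc"]), n = unname(full["n"]),
    se_a = unname(se_full["a"]),
    se_c = log(10) * 10^unname(full["lc"]) * unname(se_full["lc"]),
    se_lc = unname(se_full["lc"]),
    se_n = unname(se_full["n"]))

  new_hill_fit(params, scale, gof$rmse, gof$rsq, n_obs, converged, r, fitted,
               dat, if (is.null(rob)) NULL else rob$vcov,
               if (is.null(rob)) NA_integer_ else rob$df)
}

#' Fit the reference-agonist (E2) standard curve
#'
#' The reference agonist defines the plate's response scale, so its curve
#' is fitted as a four-parameter logistic with the efficacy fixed at 1:
#' free parameters are the asymptotes `y0` and `m`, the EC50 and the Hill
#' slope. The fitted `(y0, m)` become the [reference_scale()] used to
#' normalise and fit every other curve on the plate, and the fitted EC50
#' is the nominal dose of the plate's QC wells.
#'
#' @param data Data frame with `concentration` and `response` columns for
#'   the reference standard series.
#' @param init Optional starting values (`y0`, `m`, `c`, `n`).
#' @return A list with elements `scale` (the fitted [reference_scale()]),
#'   `ec50` and `fit` (a `hill_fit` whose parameter table carries
#'   `y0` and `m`).
#' @export
fit_e2_reference <- function(data, init = NULL) {
  dat <- check_fit_data(data)
  conc <- dat$concentration; resp <- dat$response
  if (stats::sd(resp) == 0) {
    stop("Reference series has constant response; cannot define a scale.",
         call. = FALSE)
  }
  yb <- tapply(resp, conc, mean)
  init0 <- c(y0 = max(min(yb), 0), m = max(yb),
             lc = log10(as.numeric(names(yb))[which.min(abs(yb - (min(yb) + max(yb)) / 2))]),
             n = 1)
  if (!is.null(init)) {
    init <- as.list(init)
    for (nm in c("y0", "m", "n")) if (!is.null(init[[nm]])) init0[nm] <- init[[nm]]
    if (!is.null(init$c)) init0["lc"] <- log10(init$c)
  }
  lower <- c(y0 = 0, m = 10, lc = log10(min(conc)) - 2, n = 0.1)
  upper <- c(y0 = min(50, init0["m"]), m = 400, lc = log10(max(conc)) + 2, n = 10)
  init0 <- pmin(pmax(init0, lower), upper)

  model_fn <- function(par) {
    sc <- list(y0 = par[["y0"]], m = par[["m"]])
    u <- exp(par[["n"]] * (log(conc) - log(10^par[["lc"]])))
    frac <- ifelse(is.infinite(u), 1, u / (1 + u))
    sc$y0 + (sc$m - sc$y0) * frac
  }
  resid_fn <- function(par) resp - model_fn(par)
  starts <- starts_around(init0)
  fit <- lm_engine(resid_fn, starts, lower, upper)
  if (is.null(fit)) stop("Reference curve fit failed to converge.", call. = FALSE)

  par <- fit$par
  fitted <- model_fn(par)
  r <- resp - fitted
  gof <- goodness_of_fit(resp, fitted)
  J <- num_jacobian(function(p) -resid_fn(p), par)
  rob <- robust_vcov(J, r)
  se <- if (is.null(rob)) rep(NA_real_, 4) else sqrt(pmax(diag(rob$vcov), 0))
  names(se) <- names(par)

  sc <- reference_scale(y0 = par[["y0"]], m = par[["m"]])
  params <- tibble::tibble(
    id = "E2", a = 1, c = 10^par[["lc"]], n = par[["n"]],
    y0 = par[["y0"]], m = par[["m"]],
    se_a = 0, se_c = log(10) * 10^par[["lc"]] * se[["lc"]],
    se_lc = se[["lc"]], se_n = se[["n"]],
    se_y0 = se[["y0"]], se_m = se[["m"]])
  ft <- new_hill_fit(params, sc, gof$rmse, gof$rsq, length(resp),
                     fit$info %in% 1:4 && !is.null(rob), r, fitted, dat,
                     if (is.null(rob)) NULL else rob$vcov,
                     if (is.null(rob)) NA_integer_ else rob$df,
                     kind = "reference")
  list(scale = sc, ec50 = 10^par[["lc"]], fit = ft)
}

#' Fit the multi-ligand (GRA) response to a mixture curve
#'
#' Fits the multi-ligand Hill generalisation to an observed mixture
#' concentration-response series, with component doses tied to the total
#' by the mixture's molar fractions (`x_i = f_i * T`). Per-component
#' `(a_i, c_i, n_i)` are estimated jointly; with `share_params = TRUE` a
#' single `(a, c, n)` triple is shared across components, appropriate when
#' the components are known or assumed to behave identically (and the only
#' identifiable choice for such designs).
#'
#' @param data Data frame with `concentration` (total molar) and
#'   `response` columns.
#' @param mix A [mixture()]; its `a`, `c`, `n` columns (if present) seed
#'   the optimiser.
#' @param scale A [reference_scale()].
#' @param share_params Share one `(a, c, n)` across components?
#' @return A `hill_fit` (kind `"gra"`) whose `params` tibble has one row
#'   per component (or a single `"shared"` row).
#' @export
fit_gra <- function(data, mix, scale = reference_scale(), share_params = FALSE) {
  dat <- check_fit_data(data)
  mix <- as_mixture(mix)
  conc <- dat$concentration; resp <- dat$response
  k <- nrow(mix)
  if (stats::sd(resp) == 0) {
    return(new_hill_fit(
      params = tibble::tibble(id = mix$id, a = NA_real_, c = NA_real_,
                              n = NA_real_),
      scale = scale, rmse = NA_real_, rsq = NA_real_, n_obs = length(resp),
      converged = FALSE, residuals = rep(NA_real_, length(resp)),
      fitted = rep(NA_real_, length(resp)), data = dat, vcov = NULL,
      df = NA_integer_, note = "degenerate input: constant response",
      kind = "gra"))
  }

  init1 <- default_hill_init(conc, resp, scale)
  a0 <- if (!is.null(mix[["a"]])) mix$a else rep(init1[["a"]], k)
  c0 <- if (!is.null(mix[["c"]])) mix$c else rep(10^init1[["lc"]] , k) * mix$fraction
  n0 <- if (!is.null(mix[["n"]])) mix$n else rep(1, k)

  if (share_params) {
    init0 <- c(a = mean(a0), lc = log10(stats::median(c0)), n = mean(n0))
    lower <- c(a = 0, lc = log10(min(conc) * min(mix$fraction[mix$fraction > 0])) - 2,
               n = 0.1)
    upper <- c(a = 3, lc = log10(max(conc)) + 2, n = 10)
    expand <- function(par) {
      tibble::tibble(a = rep(par[["a"]], k), c = rep(10^par[["lc"]], k),
                     n = rep(par[["n"]], k))
    }
  } else {
    init0 <- stats::setNames(c(a0, log10(c0), n0),
                             c(paste0("a", 1:k), paste0("lc", 1:k), paste0("n", 1:k)))
    lower <- stats::setNames(c(rep(0, k), rep(log10(min(conc)) - 4, k), rep(0.1, k)),
                             names(init0))
    upper <- stats::setNames(c(rep(3, k), rep(log10(max(conc)) + 4, k), rep(10, k)),
                             names(init0))
    expand <- function(par) {
      tibble::tibble(a = par[paste0("a", 1:k)],
                     c = 10^par[paste0("lc", 1:k)],
                     n = par[paste0("n", 1:k)])
    }
  }
  doses <- outer(mix$fraction, conc)          # k x n_obs
  model_fn <- function(par) {
    p <- expand(par)
    gra_response(p, doses, scale)
  }
  resid_fn <- function(par) resp - model_fn(par)
  starts <- if (share_params) starts_around(init0) else {
    shifts <- seq(-1, 1, length.out = 3)
    c(list(init0), lapply(shifts, function(s) {
      st <- init0; st[grepl("^lc", names(st))] <- st[grepl("^lc", names(st))] + s; st
    }))
  }
  fit <- lm_engine(resid_fn, starts, lower, upper)
  out <- finish_fit(fit, model_fn, resid_fn, names(init0), NULL, conc, resp,
                    scale, dat, id = "fit")
  # rebuild the parameter table per component
  if (!is.null(fit)) {
    p <- expand(fit$par)
    p$id <- if (share_params) rep("shared", k) else mix$id
    p$fraction <- mix$fraction
    if (share_params) {
      p$se_a <- rep(out$params$se_a[1] %||% NA_real_, k)
    }
    out$params <- tibble::as_tibble(p[, c("id", "fraction", "a", "c", "n")])
  }
  out$kind <- "gra"
  out
}

#' Goodness of fit of a predicted curve
#'
#' Root-mean-square error and coefficient of determination between
#' observed and predicted percent-activity values:
#' `rmse = sqrt(mean((obs - pred)^2))` (denominator `n`, an average
#' difference) and `rsq = 1 - SSres/SStot` with `SStot` about the observed
#' mean. `rsq` is `NA` when the observations have zero variance.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A one-row tibble with `rmse`, `rsq`, `n_obs`.
#' @examples
#' goodness_of_fit(c(0, 50, 100), c(10, 50, 90))  # rmse 8.165, rsq 0.96
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length.", call. = FALSE)
  }
  r <- observed - predicted
  ssres <- sum(r^2)
  sstot <- sum((observed - mean(observed))^2)
  tibble::tibble(
    rmse = sqrt(ssres / length(r)),
    rsq = if (sstot > 0) 1 - ssres / sstot else NA_real_,
    n_obs = length(r))
}

#' Classify sample activity against assay detection thresholds
#'
#' Activity below 10% of the reference maximum is not detectable (< LoD);
#' below 20% it is below the limit of quantification (< LoQ); at or above
#' 20% it is quantifiable. Thresholds are exclusive from below: exactly
#' 10% is `below_LoQ`, exactly 20% is `quantifiable`.
#'
#' @param max_observed Maximal observed percent activity (vectorised).
#' @return Character vector with levels `not_detected`, `below_LoQ`,
#'   `quantifiable`.
#' @examples
#' classify_activity(c(8, 15, 20, 150))
#' @export
classify_activity <- function(max_observed) {
  if (any(!is.finite(max_observed))) {
    stop("`max_observed` must be finite.", call. = FALSE)
  }
  dplyr::case_when(
    max_observed < 10 ~ "not_detected",
    max_observed < 20 ~ "below_LoQ",
    TRUE ~ "quantifiable")
}

#' QC-well recovery report
#'
#' QC wells are dosed at the reference agonist's EC50, so their nominal
#' response is the curve midpoint `y0 + (m - y0)/2`. Recovery is the
#' observed response over that nominal value, in percent; recoveries
#' between 89% and 120% are flagged as passing, the range considered
#' satisfactory for the reference agonist.
#'
#' @param qc_responses Observed percent-activity values of the QC wells.
#' @param scale The plate's [reference_scale()].
#' @return A one-row tibble with `e2_recovery` (mean recovery, %),
#'   `qc_pass`, and `n_wells`.
#' @export
qc_report <- function(qc_responses, scale = reference_scale()) {
  if (any(!is.finite(qc_responses))) {
    stop("QC responses must be finite.", call. = FALSE)
  }
  nominal <- scale$y0 + span(scale) / 2
  rec <- 100 * mean(qc_responses - scale$y0) / (nominal - scale$y0)
  tibble::tibble(e2_recovery = rec,
                 qc_pass = rec >= 89 && rec <= 120,
                 n_wells = length(qc_responses))
}
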