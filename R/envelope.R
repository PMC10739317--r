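#' Specify per-parameter uncertainty for Monte-Carlo propagation
#'
#' One row per (component, parameter) pair. `dist` is `"normal"`
#' (`p1` = mean, `p2` = sd) or `"uniform"` (`p1` = lower, `p2` = upper).
#' Draws are truncated to parameter validity (`a >= 0`, `c > 0`, `n > 0`)
#' by resampling.
#'
#' `uncertainty_uniform()` builds a relative-width uniform spec around a
#' mixture's own parameters (the default when no fitted standard errors
#' exist); `uncertainty_from_fits()` builds normal specs from fitted
#' single-compound curves (mean = estimate, sd = robust SE).
#'
#' @param mix A [mixture()].
#' @param rel Relative half-width, e.g. `0.1` for +/-10%.
#' @return A tibble with columns `id`, `param`, `dist`, `p1`, `p2`.
#' @export
uncertainty_uniform <- function(mix, rel = 0.1) {
  mix <- as_mixture(mix)
  tidyr::crossing(id = mix$id, param = c("a", "c", "n")) |>
    dplyr::left_join(mix[, c("id", "a", "c", "n")], by = "id") |>
    dplyr::mutate(
      centre = dplyr::case_when(.data$param == "a" ~ .data$a,
                                .data$param == "c" ~ .data$c,
                                TRUE ~ .data$n),
      dist = "uniform",
      p1 = .data$centre * (1 - rel),
      p2 = .data$centre * (1 + rel)) |>
    dplyr::select("id", "param", "dist", "p1", "p2")
}

#' @rdname uncertainty_uniform
#' @param fits Named list of `hill_fit` objects, one per mixture
#'   component (names matching the mixture `id`s).
#' @export
uncertainty_from_fits <- function(fits) {
  purrr::imap_dfr(fits, function(f, nm) {
    stopifnot(inherits(f, "hill_fit"))
    p <- f$params
    tibble::tibble(
      id = nm, param = c("a", "c", "n"), dist = "normal",
      p1 = c(p$a[1], p$c[1], p$n[1]),
      p2 = c(p$se_a[1], p$se_c[1], p$se_n[1]))
  })
}

draw_params <- function(unc, mix, n_sims) {
  k <- nrow(mix)
  draw_one <- function(id, param, n) {
    row <- unc[unc$id == id & unc$param == param, ]
    if (nrow(row) == 0L) {  # parameter held fixed at the mixture value
      centre <- mix[[param]][mix$id == id]
      return(rep(centre, n))
    }
    if (nrow(row) > 1L) {
      stop("Duplicate uncertainty spec for ", id, "/", param, ".", call. = FALSE)
    }
    if (row$dist == "normal") {
      stats::rnorm(n, row$p1, row$p2)
    } else if (row$dist == "uniform") {
      stats::runif(n, row$p1, row$p2)
    } else {
      stop("Unknown distribution '", row$dist, "' (use normal or uniform).",
           call. = FALSE)
    }
  }
  A <- C <- N <- matrix(0, k, n_sims)
  for (i in seq_len(k)) {
    A[i, ] <- draw_one(mix$id[i], "a", n_sims)
    C[i, ] <- draw_one(mix$id[i], "c", n_sims)
    N[i, ] <- draw_one(mix$id[i], "n", n_sims)
  }
  valid <- colSums(A < 0) == 0 & colSums(C <= 0) == 0 & colSums(N <= 0) == 0
  list(A = A, C = C, N = N, valid = valid)
}

#' Monte-Carlo 95% prediction envelope for a mixture curve
#'
#' Propagates parameter uncertainty through the CA or GRA prediction:
#' `n_sims` parameter sets are drawn from the per-parameter distributions,
#' the full mixture curve is predicted for each draw, and pointwise 2.5%,
#' 50% and 97.5% quantiles form the envelope. A measured curve that
#' escapes the envelope rejects the additivity hypothesis (see
#' [additivity_test()]).
#'
#' Draws violating parameter validity are resampled; if more than half of
#' the initial draws are invalid the uncertainty specification is
#' considered inconsistent and an error is raised. Under CA, each draw's
#' curve is built from a 512-level effect grid and levels beyond a draw's
#' weakest component are capped at that draw's reachable ceiling.
#'
#' @param design A [mixture_design()].
#' @param uncertainty Uncertainty spec (see [uncertainty_uniform()]).
#' @param model `"GRA"` or `"CA"`.
#' @param n_sims Number of draws (>= 1000).
#' @param seed Integer seed; the envelope is reproducible given the seed.
#' @param scale A [reference_scale()].
#' @return An `mc_envelope` object; its `band` tibble has `concentration`,
#'   `lower`, `median`, `upper`.
#' @export
mc_envelope <- function(design, uncertainty, model = c("GRA", "CA"),
                        n_sims = 10000, seed, scale = reference_scale()) {
  model <- match.arg(model)
  stopifnot(inherits(design, "mixture_design"))
  if (n_sims < 1000) stop("`n_sims` must be >= 1000.", call. = FALSE)
  if (missing(seed)) stop("A `seed` is required for reproducibility.", call. = FALSE)
  if (model == "CA" && design$kind == "coexposure_with_reference") {
    stop("CA envelopes are undefined for co-exposure designs.", call. = FALSE)
  }

  mix <- design$mix
  sims <- withr::with_seed(seed, {
    d <- draw_params(uncertainty, mix, n_sims)
    if (mean(d$valid) < 0.5) {
      stop("More than 50% of parameter draws were invalid (a >= 0, c > 0, ",
           "n > 0); the uncertainty specification is inconsistent.",
           call. = FALSE)
    }
    tries <- 0L
    while (any(!d$valid) && tries < 50L) {   # resample invalid columns
      redo <- draw_params(uncertainty, mix, sum(!d$valid))
      idx <- which(!d$valid)
      d$A[, idx] <- redo$A; d$C[, idx] <- redo$C; d$N[, idx] <- redo$N
      d$valid[idx] <- redo$valid
      tries <- tries + 1L
    }
    if (any(!d$valid)) {
      stop("Could not obtain valid parameter draws after resampling.",
           call. = FALSE)
    }
    d
  })

  Y <- if (model == "GRA") {
    gra_draw_curves(design, sims, scale)
  } else {
    ca_draw_curves(design, sims, scale)
  }
  qs <- apply(Y, 1L, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE, type = 7)
  band <- tibble::tibble(concentration = design$grid,
                         lower = qs[1, ], median = qs[2, ], upper = qs[3, ])
  structure(list(band = band, model = model, n_sims = n_sims, seed = seed,
                 design = design, scale = scale),
            class = "mc_envelope")
}

# GRA curves for all draws: accumulate per-component occupancy terms.
# Returns an m x n_sims matrix (grid points x draws).
gra_draw_curves <- function(design, sims, scale) {
  grid <- design$grid
  m <- length(grid); S <- ncol(sims$A)
  comp <- design_doses(design)
  k <- nrow(comp$ligands)
  num <- matrix(0, m, S); den <- matrix(1, m, S)
  for (i in seq_len(k)) {
    if (i <= nrow(design$mix)) {
      a <- sims$A[i, ]; cc <- sims$C[i, ]; nn <- sims$N[i, ]
    } else {  # fixed reference component in co-exposure designs
      a <- rep(comp$ligands$a[i], S); cc <- rep(comp$ligands$c[i], S)
      nn <- rep(comp$ligands$n[i], S)
    }
    xi <- comp$doses[i, ]
    lx <- log(xi)                                  # -Inf at zero dose is fine
    Lg <- outer(lx, -log(cc), `+`) * rep(nn, each = m)
    U <- exp(pmin(Lg, 700))                        # guard overflow
    num <- num + U * rep(a, each = m)
    den <- den + U
  }
  scale$y0 + span(scale) * num / den
}

# CA curves for all draws via a shared effect-level grid: for each draw the
# mixture ECx is vectorised over 512 levels, then the response at the
# design grid is linear-interpolated on log-concentration. Levels above a
# draw's weakest component are dropped, capping that draw's curve at its
# reachable ceiling.
ca_draw_curves <- function(design, sims, scale, n_levels = 512L) {
  grid <- design$grid
  m <- length(grid); S <- ncol(sims$A)
  f <- design$mix$fraction
  Y <- matrix(NA_real_, m, S)
  lgrid <- log(grid)
  for (s in seq_len(S)) {
    a <- sims$A[, s]; cc <- sims$C[, s]; nn <- sims$N[, s]
    ceiling_r <- min(a)
    r <- seq(1e-6, ceiling_r * (1 - 1e-9), length.out = n_levels)
    ecx <- sapply(seq_along(a), function(i) cc[i] * (r / (a[i] - r))^(1 / nn[i]))
    ecx_mix <- 1 / as.numeric(ecx^-1 %*% f)
    yy <- scale$y0 + span(scale) * r               # r is a fraction of span
    Y[, s] <- stats::approx(log(ecx_mix), yy, xout = lgrid, rule = 2)$y
  }
  Y
}

#' @export
print.mc_envelope <- function(x, ...) {
  cat("<mc_envelope>", x$model, "model,", x$n_sims, "draws, seed", x$seed, "\n")
  print(x$band)
  invisible(x)
}

#' @describeIn mc_envelope Tidy the envelope band.
#' @param x An `mc_envelope`.
#' @param ... Unused.
#' @export
tidy.mc_envelope <- function(x, ...) x$band

#' Test an observed mixture curve against a Monte-Carlo envelope
#'
#' Flags each observed mean response as `inside`, `above` or `below` the
#' envelope's pointwise 95% band and renders an overall verdict:
#' additivity is rejected when at least two consecutive points fall
#' outside on the same side within the curve's dynamic range (envelope
#' median between 10% and 90% of the reference span). Excursions above
#' the band suggest synergy, below antagonism; isolated single-point
#' excursions are recorded but do not flip the verdict.
#'
#' Observed responses are averaged per concentration and interpolated
#' onto the envelope grid by monotone cubic interpolation in
#' log-concentration; the concentration ranges must overlap.
#'
#' @param observed Data frame with `concentration` and `response`
#'   (replicates as extra rows).
#' @param envelope An [mc_envelope()].
#' @return An `additivity_verdict` object; `tidy()` gives per-point flags,
#'   `glance()` the overall verdict and counts.
#' @export
additivity_test <- function(observed, envelope) {
  stopifnot(inherits(envelope, "mc_envelope"))
  obs <- check_fit_data_loose(observed)
  mean_obs <- obs |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop") |>
    dplyr::arrange(.data$concentration)
  band <- envelope$band
  overlap <- band$concentration >= min(mean_obs$concentration) &
    band$concentration <= max(mean_obs$concentration)
  if (!any(overlap)) {
    stop("Observed and envelope concentration ranges do not overlap.",
         call. = FALSE)
  }
  # monoH.FC is shape-preserving between knots and, unlike Hyman filtering,
  # accepts the locally non-monotone means that assay noise produces
  interp <- stats::splinefun(log(mean_obs$concentration), mean_obs$response,
                             method = "monoH.FC")
  grid <- band$concentration[overlap]
  yobs <- interp(log(grid))
  lower <- band$lower[overlap]; upper <- band$upper[overlap]
  medn <- band$median[overlap]
  flag <- dplyr::case_when(yobs > upper ~ "above",
                           yobs < lower ~ "below",
                           TRUE ~ "inside")
  sc <- envelope$scale
  dynamic <- medn >= sc$y0 + 0.1 * span(sc) & medn <= sc$y0 + 0.9 * span(sc)

  flags <- tibble::tibble(concentration = grid, observed = yobs,
                          lower = lower, median = medn, upper = upper,
                          flag = flag, in_dynamic_range = dynamic)
  overall <- decide_verdict(flag, dynamic)
  structure(list(flags = flags, overall = overall,
                 counts = table(factor(flag, c("inside", "above", "below"))),
                 model = envelope$model, seed = envelope$seed),
            class = "additivity_verdict")
}

# >= 2 consecutive same-side excursions within the dynamic range reject
# additivity; otherwise additive.
decide_verdict <- function(flag, dynamic) {
  for (side in c("above", "below")) {
    hits <- flag == side & dynamic
    runs <- rle(hits)
    if (any(runs$lengths[runs$values] >= 2)) {
      return(if (side == "above") "synergy_candidate" else "antagonism_candidate")
    }
  }
  "additive"
}

check_fit_data_loose <- function(data) {
  if (!is.data.frame(data)) stop("`observed` must be a data frame.", call. = FALSE)
  need <- setdiff(c("concentration", "response"), names(data))
  if (length(need)) {
    stop("`observed` is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dat <- tibble::as_tibble(data)[c("concentration", "response")]
  dat <- dat[is.finite(dat$response), ]
  if (any(dat$concentration <= 0)) {
    stop("Concentrations must be > 0.", call. = FALSE)
  }
  dat
}

#' @export
print.additivity_verdict <- function(x, ...) {
  cat("<additivity_verdict>", x$overall, "(", x$model, "envelope )\n")
  cat("  points inside/above/below:", paste(x$counts, collapse = "/"), "\n")
  invisible(x)
}

#' @describeIn additivity_test Per-point flags as a tibble.
#' @param x An `additivity_verdict`.
#' @param ... Unused.
#' @export
tidy.additivity_verdict <- function(x, ...) x$flags

#' @describeIn additivity_test One-row summary (overall verdict + counts).
#' @export
glance.additivity_verdict <- function(x, ...) {
  tibble::tibble(overall = x$overall,
                 n_inside = as.integer(x$counts[["inside"]]),
                 n_above = as.integer(x$counts[["above"]]),
                 n_below = as.integer(x$counts[["below"]]),
                 model = x$model)
}

#' Compare CA and GRA predictions against an observed curve
#'
#' Computes RMSE and RSQ of each model's predicted curve against the
#' observed mean responses on a common concentration grid and names the
#' winner (lower RMSE); differences below 1e-9 percent activity are
#' reported as a tie.
#'
#' @param observed Data frame with `concentration` and `response`.
#' @param ca_pred,gra_pred Predicted curves (tibbles with `concentration`
#'   and `response`) on the same grid as the observed means.
#' @return A tibble with one row per model plus attribute `winner`.
#' @export
compare_models <- function(observed, ca_pred, gra_pred) {
  obs <- check_fit_data_loose(observed) |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop") |>
    dplyr::arrange(.data$concentration)
  score <- function(pred, label) {
    pred <- dplyr::arrange(tibble::as_tibble(pred), .data$concentration)
    if (nrow(pred) != nrow(obs) ||
        any(abs(log(pred$concentration) - log(obs$concentration)) > 1e-8)) {
      stop("`", label, "` is not on the observed concentration grid.",
           call. = FALSE)
    }
    ok <- is.finite(pred$response)
    dplyr::mutate(goodness_of_fit(obs$response[ok], pred$response[ok]),
                  model = label, .before = 1)
  }
  out <- dplyr::bind_rows(score(ca_pred, "CA"), score(gra_pred, "GRA"))
  d <- out$rmse[out$model == "CA"] - out$rmse[out$model == "GRA"]
  attr(out, "winner") <- if (abs(d) <= 1e-9) "tie" else if (d > 0) "GRA" else "CA"
  out
}
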