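#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted Hill / GRA curve
#'
#' One row per parameter with the estimate, robust standard error and
#' Wald confidence interval. The EC50 interval is computed on the log10
#' scale (where the sampling distribution is closest to normal) and
#' back-transformed.
#'
#' @param x A `hill_fit`.
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble with columns `component`, `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.hill_fit <- function(x, conf.level = 0.95, ...) {
  p <- x$params
  tq <- if (is.finite(x$df %||% NA)) stats::qt(1 - (1 - conf.level) / 2, x$df)
        else NA_real_
  rows <- lapply(seq_len(nrow(p)), function(i) {
    terms <- c("a", "c", "n")
    if (!is.null(p[["y0"]])) terms <- c(terms, "y0", "m")
    purrr::map_dfr(terms, function(tm) {
      est <- p[[tm]][i]
      se <- p[[paste0("se_", tm)]][i] %||% NA_real_
      if (tm == "c" && !is.null(p[["se_lc"]])) {
        lc <- log10(est); half <- tq * p$se_lc[i]
        lo <- 10^(lc - half); hi <- 10^(lc + half)
      } else {
        lo <- est - tq * se; hi <- est + tq * se
      }
      tibble::tibble(component = p$id[i], term = tm, estimate = est,
                     std.error = se, conf.low = lo, conf.high = hi)
    })
  })
  dplyr::bind_rows(rows)
}

#' One-row fit summary
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with `rmse`, `rsq`, `n_obs`, `converged`, `df`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, rsq = x$rsq, n_obs = x$n_obs,
                 converged = x$converged, df = x$df %||% NA_integer_)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>", x$kind, "fit,", x$n_obs, "observations,",
      if (x$converged) "converged" else paste0("NOT converged",
        if (!is.null(x$note)) paste0(" (", x$note, ")")), "\n")
  if (x$converged || all(is.finite(x$params$a))) {
    print(x$params)
    cat("  rmse =", format(x$rmse, digits = 4),
        " rsq =", format(x$rsq, digits = 4), "\n")
  }
  invisible(x)
}

#' Plot a fitted concentration-response curve
#'
#' Observed points with the fitted sigmoid on a log concentration axis.
#'
#' @param object A `hill_fit`.
#' @param n_curve Number of points for the fitted line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, n_curve = 200, ...) {
  d <- object$data
  xs <- 10^seq(log10(min(d$concentration)), log10(max(d$concentration)),
               length.out = n_curve)
  curve <- tibble::tibble(
    concentration = xs,
    response = if (object$kind == "gra") {
      mixp <- object$params
      gra_response(mixp[, c("a", "c", "n")],
                   outer(mixp$fraction, xs), object$scale)
    } else if (!is.null(object$params[["y0"]])) {
      p <- object$params
      sc <- reference_scale(p$y0[1], p$m[1])
      hill_response(p[1, c("a", "c", "n")], xs, sc)
    } else {
      hill_response(object$params[1, c("a", "c", "n")], xs, object$scale)
    })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (M)", y = "Activity (% of reference max)") +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo prediction envelope
#'
#' The 95% band with its median curve, optionally overlaid with observed
#' responses.
#'
#' @param object An `mc_envelope`.
#' @param observed Optional data frame with `concentration`, `response`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_envelope <- function(object, observed = NULL, ...) {
  b <- object$band
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$concentration)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Total concentration (M)",
                  y = "Activity (% of reference max)",
                  title = paste0(object$model, " 95% Monte-Carlo envelope (",
                                 object$n_sims, " draws)")) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(observed),
      ggplot2::aes(x = .data$concentration, y = .data$response),
      inherit.aes = FALSE, alpha = 0.6)
  }
  p
}
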