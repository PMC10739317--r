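#' Hill concentration-response for a single ligand
#'
#' Evaluates the generalised Hill equation
#' \deqn{y = y_0 + (m - y_0)\, \frac{a\,(x/c)^n}{1 + (x/c)^n}}
#' where `a` is the ligand's efficacy relative to the reference span,
#' `c` its EC50 and `n` its Hill slope. Zero dose returns the baseline
#' `y0`; the high-dose plateau is `y0 + (m - y0) a`.
#'
#' @param ligand A single ligand (one-row data frame or list with `a`,
#'   `c`, `n`; see [ligand()]).
#' @param x Molar concentration(s), finite and `>= 0`.
#' @param scale A [reference_scale()].
#' @return Percent activity, same length as `x`.
#' @examples
#' e2 <- ligand(a = 1, c = 5e-12, n = 1, id = "E2")
#' hill_response(e2, c(0, 5e-12, 5e-9))   # 0, 50, ~100
#' @export
hill_response <- function(ligand, x, scale = reference_scale()) {
  lig <- as_ligand_tbl(ligand)
  if (nrow(lig) != 1L) {
    stop("`hill_response()` takes one ligand; use `gra_response()` for several.",
         call. = FALSE)
  }
  check_dose(x)
  # single-ligand special case of the multi-ligand response, so the two
  # agree exactly by construction
  gra_response(lig, matrix(x, nrow = 1L), scale)
}

check_dose <- function(x, what = "x") {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("`", what, "` must be numeric.", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`", what, "` must be finite and >= 0.", call. = FALSE)
  }
  invisible(x)
}

#' Multi-ligand receptor response (generic response addition, GRA)
#'
#' Evaluates the mass-action generalisation of the Hill equation for
#' several ligands competing for one receptor:
#' \deqn{y = y_0 + (m - y_0)\,
#'   \frac{\sum_i a_i (x_i/c_i)^{n_i}}{1 + \sum_i (x_i/c_i)^{n_i}}}
#' Each ligand keeps its own efficacy, potency and slope; a pure
#' antagonist (`a = 0`) occupies receptor (denominator) without
#' activating it (numerator), so adding one can only lower the response.
#' With a single ligand this reduces exactly to [hill_response()].
#'
#' The occupancy terms are accumulated on the log scale and normalised by
#' the largest term, so saturating doses evaluate to the correct plateau
#' rather than overflowing to `NaN`.
#'
#' @param ligands Ligand table, one row per ligand (columns `a`, `c`, `n`).
#' @param doses Molar concentrations: a vector with one dose per ligand
#'   (one response), or a matrix with `nrow(ligands)` rows whose columns
#'   are dose combinations (one response per column).
#' @param scale A [reference_scale()].
#' @return Percent activity; one value per dose combination.
#' @examples
#' lig <- data.frame(id = c("ag", "ant"), a = c(1, 0), c = c(1, 1), n = c(1, 1))
#' gra_response(lig, c(1, 0))   # agonist alone at its EC50: 50
#' gra_response(lig, c(1, 9))   # antagonist competes: 100/11
#' @export
gra_response <- function(ligands, doses, scale = reference_scale()) {
  lig <- as_ligand_tbl(ligands)
  k <- nrow(lig)
  if (is.matrix(doses)) {
    if (nrow(doses) != k) {
      stop("`doses` matrix must have one row per ligand.", call. = FALSE)
    }
    X <- doses
  } else {
    if (k == 1L) {
      X <- matrix(as.numeric(doses), nrow = 1L)
    } else {
      if (length(doses) != k) {
        stop("Need one dose per ligand (", k, " ligands, ", length(doses),
             " doses).", call. = FALSE)
      }
      X <- matrix(as.numeric(doses), nrow = k)
    }
  }
  check_dose(X, "doses")
  # log occupancy l_i = n_i * log(x_i / c_i); x = 0 gives l = -Inf (no binding)
  L <- lig$n * (log(X) - log(lig$c))            # k x m, recycled by column
  if (k == 1L) dim(L) <- dim(X)
  M <- apply(L, 2L, function(col) max(col, 0))  # shift keeps exp() in range
  E <- exp(sweep(L, 2L, M))                     # e^{l_i - M}
  num <- colSums(lig$a * E)
  den <- exp(-M) + colSums(E)
  scale$y0 + span(scale) * num / den
}

#' Effective concentration for a given effect level (ECx)
#'
#' Inverts the Hill curve: the concentration at which a ligand alone
#' produces `X` percent of the reference span. Solving the Hill equation
#' for `x` with `r = X/100` gives the closed form
#' `c * (r / (a - r))^(1/n)`, defined only for `0 < r < a`: a partial
#' agonist (`a < 1`) can never reach effect levels above `100 a`.
#'
#' @param ligand A single ligand.
#' @param X Effect level in percent of the reference span, `0 < X < 100 a`.
#' @return Molar concentration.
#' @examples
#' ecx_from_hill(ligand(a = 1, c = 1e-8, n = 1), 50)   # EC50 == c
#' @export
ecx_from_hill <- function(ligand, X) {
  lig <- as_ligand_tbl(ligand)
  if (nrow(lig) != 1L) stop("`ecx_from_hill()` takes one ligand.", call. = FALSE)
  if (!is.numeric(X) || length(X) != 1L || !is.finite(X)) {
    stop("`X` must be a single finite effect level in percent.", call. = FALSE)
  }
  r <- X / 100
  if (r <= 0) stop("Effect level `X` must be positive.", call. = FALSE)
  if (r >= lig$a) {
    stop("Unreachable effect level: X = ", X, "% exceeds the maximal effect ",
         "of ligand '", lig$id, "' (efficacy a = ", lig$a, ", ceiling ",
         100 * lig$a, "%).", call. = FALSE)
  }
  lig$c * (r / (lig$a - r))^(1 / lig$n)
}

#' Concentration-addition effective concentration of a mixture
#'
#' Under concentration addition (CA) every component is treated as a
#' dilution of the others, and the mixture concentration producing effect
#' `X` is the fraction-weighted harmonic combination
#' \deqn{EC_{X,\mathrm{mix}} = \left(\sum_i f_i / EC_{X,i}\right)^{-1}}
#' with `f_i` the molar fraction of component `i`. The level `X` must be
#' reachable by every component; partial agonists bound the levels CA can
#' describe, which is the model's documented limitation.
#'
#' @param mix A [mixture()].
#' @param X Effect level in percent of the reference span.
#' @return Molar concentration of total mixture.
#' @examples
#' mx <- mixture(data.frame(a = c(1, 1), c = c(1e-6, 3e-6), n = c(1, 1)),
#'               fractions = c(0.5, 0.5))
#' ca_mixture_ecx(mx, 50)    # 1.5e-6
#' @export
ca_mixture_ecx <- function(mix, X) {
  mix <- as_mixture(mix)
  r <- X / 100
  bad <- mix$a <= r
  if (any(bad)) {
    stop("Effect level X = ", X, "% is unreachable for component(s): ",
         paste0(mix$id[bad], " (a = ", mix$a[bad], ")", collapse = ", "),
         ". Concentration addition is undefined above the weakest ",
         "component's maximal effect.", call. = FALSE)
  }
  ecx <- purrr::map_dbl(seq_len(nrow(mix)), function(i) {
    ecx_from_hill(mix[i, ], X)
  })
  1 / sum(mix$fraction / ecx)
}

# Bracketed root-finding on log10-concentration. f must be monotone over the
# bracket; the bracket is grown geometrically if the root is not yet
# straddled. Relative tolerance ~1e-11 on the concentration.
solve_conc <- function(f, lower, upper, max_grow = 6L) {
  lo <- log10(lower); hi <- log10(upper)
  flo <- f(10^lo); fhi <- f(10^hi)
  grow <- 0L
  while (sign(flo) == sign(fhi) && grow < max_grow) {
    lo <- lo - 2; hi <- hi + 2; grow <- grow + 1L
    flo <- f(10^lo); fhi <- f(10^hi)
  }
  if (sign(flo) == sign(fhi)) {
    stop("Root not bracketed on [1e", round(lo), ", 1e", round(hi),
         "] M: f(lower) = ", signif(flo, 4), ", f(upper) = ", signif(fhi, 4),
         ".", call. = FALSE)
  }
  r <- stats::uniroot(function(l) f(10^l), lower = lo, upper = hi,
                      tol = 1e-11, maxiter = 200L)
  10^r$root
}

#' Apparent EC50 of an agonist in the presence of a competitive antagonist
#'
#' A pure antagonist (`a = 0`) occupies receptor without activating it, so
#' the agonist curve keeps its plateau but shifts right. This solves the
#' multi-ligand response for the agonist concentration producing half of
#' the agonist's own maximal span at a fixed antagonist dose. For unit Hill
#' slopes the shift has the Schild/Gaddum closed form
#' `c_ag * (1 + x_ant / c_ant)`, which the numerical root reproduces.
#'
#' @param agonist Agonist ligand (`a > 0`).
#' @param antagonist Pure antagonist ligand (`a = 0`).
#' @param x_ant Molar antagonist concentration, `>= 0`.
#' @param scale A [reference_scale()].
#' @return Apparent agonist EC50 (molar); non-decreasing in `x_ant`.
#' @export
apparent_ec50_shift <- function(agonist, antagonist, x_ant,
                                scale = reference_scale()) {
  ag <- as_ligand_tbl(agonist); ant <- as_ligand_tbl(antagonist)
  if (ant$a != 0) stop("`antagonist` must have efficacy a = 0.", call. = FALSE)
  if (ag$a <= 0) stop("`agonist` must have efficacy a > 0.", call. = FALSE)
  check_dose(x_ant, "x_ant")
  if (x_ant == 0) return(ag$c)
  target <- scale$y0 + span(scale) * ag$a / 2
  pair <- dplyr::bind_rows(ag, ant)
  f <- function(x) gra_response(pair, c(x, x_ant), scale) - target
  solve_conc(f, ag$c * 1e-6, ag$c * 1e6)
}

#' Antagonist IC50 against a fixed agonist dose
#'
#' The IC50 is the antagonist concentration halving the agonist response
#' (measured above baseline) at a fixed agonist dose. For unit Hill slopes
#' the competitive-occupancy model gives the closed form
#' `c_ant * (1 + x_ag / c_ag)`: the more agonist present, the more
#' antagonist is needed, and the inhibition can always be overcome.
#' The result does not depend on the `(y0, m)` scaling.
#'
#' @param agonist Agonist ligand (`a > 0`).
#' @param x_ag Molar agonist concentration, `> 0`.
#' @param antagonist Pure antagonist ligand (`a = 0`).
#' @param scale A [reference_scale()].
#' @return Antagonist IC50 (molar).
#' @export
ic50_of_antagonist <- function(agonist, x_ag, antagonist,
                               scale = reference_scale()) {
  ag <- as_ligand_tbl(agonist); ant <- as_ligand_tbl(antagonist)
  if (ant$a != 0) stop("`antagonist` must have efficacy a = 0.", call. = FALSE)
  if (ag$a <= 0) stop("`agonist` must have efficacy a > 0.", call. = FALSE)
  check_dose(x_ag, "x_ag")
  r0 <- hill_response(ag, x_ag, scale)
  if (r0 <= scale$y0) {
    stop("Agonist response at `x_ag` is at baseline; IC50 undefined.",
         call. = FALSE)
  }
  target <- scale$y0 + (r0 - scale$y0) / 2
  pair <- dplyr::bind_rows(ag, ant)
  f <- function(x) gra_response(pair, c(x_ag, x), scale) - target
  solve_conc(f, ant$c * 1e-8, ant$c * 1e8)
}
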