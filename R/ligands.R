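#' Reference-agonist response scale
#'
#' Responses in this package are expressed as percent activity relative to
#' the reference agonist (17beta-estradiol, E2, in an ER-CALUX assay). The
#' scale carries the lower asymptote `y0` and the upper asymptote `m` of the
#' reference curve; after plate normalisation these are conventionally 0 and
#' 100. All efficacies `a` are fractions of the span `m - y0`.
#'
#' @param y0 Baseline (lower asymptote) in percent activity, `>= 0`.
#' @param m Reference maximum (upper asymptote) in percent activity, `> y0`.
#' @return An object of class `reference_scale`.
#' @examples
#' reference_scale()          # the conventional 0--100% scale
#' reference_scale(2.5, 98)   # a plate whose blank sits at 2.5%
#' @export
reference_scale <- function(y0 = 0, m = 100) {
  if (!is.numeric(y0) || length(y0) != 1L || !is.finite(y0) || y0 < 0) {
    stop("`y0` must be a single finite number >= 0.", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= y0) {
    stop("`m` must be a single finite number greater than `y0`.", call. = FALSE)
  }
  structure(list(y0 = y0, m = m), class = "reference_scale")
}

#' @export
print.reference_scale <- function(x, ...) {
  cat("<reference_scale> y0 =", x$y0, "  m =", x$m, "(% activity)\n")
  invisible(x)
}

span <- function(scale) scale$m - scale$y0

#' Describe a ligand by efficacy, potency and Hill slope
#'
#' Builds a one-row ligand table. `a` is the maximal response as a fraction
#' of the reference span (0 for a pure antagonist, 1 for a full agonist,
#' above 1 for a supra-agonist), `c` the EC50 in molar units, and `n` the
#' Hill slope (sensitivity coefficient). The apparent dissociation constant
#' of the underlying mass-action model is `c^n` and is never stored
#' separately.
#'
#' @param a Efficacy, unitless, `>= 0`.
#' @param c Potency (EC50), molar, `> 0`.
#' @param n Hill slope, unitless, `> 0`.
#' @param id Optional compound identifier.
#' @return A one-row tibble with columns `id`, `a`, `c`, `n`.
#' @examples
#' ligand(a = 1, c = 5e-12, n = 1, id = "E2")
#' @export
ligand <- function(a, c, n, id = NULL) {
  out <- tibble::tibble(id = if (is.null(id)) "L1" else as.character(id),
                        a = as.numeric(a), c = as.numeric(c), n = as.numeric(n))
  validate_ligands(out)
}

#' Coerce to a validated ligand table
#'
#' Accepts a data frame with columns `a`, `c`, `n` (and optionally `id`,
#' `fraction`) or a named list/vector with elements `a`, `c`, `n`.
#'
#' @param x Object to coerce.
#' @return A tibble with one row per ligand.
#' @export
as_ligand_tbl <- function(x) {
  if (is.data.frame(x)) {
    out <- tibble::as_tibble(x)
  } else if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    if (!all(c("a", "c", "n") %in% names(x))) {
      stop("A ligand needs named elements `a`, `c` and `n`.", call. = FALSE)
    }
    out <- tibble::tibble(a = as.numeric(x$a), c = as.numeric(x$c),
                          n = as.numeric(x$n))
    if (!is.null(x$id)) out$id <- as.character(x$id)
  } else {
    stop("Cannot interpret `x` as a ligand table.", call. = FALSE)
  }
  if (is.null(out[["id"]])) out$id <- paste0("L", seq_len(nrow(out)))
  validate_ligands(out)
}

validate_ligands <- function(lig) {
  need <- setdiff(c("a", "c", "n"), names(lig))
  if (length(need)) {
    stop("Ligand table is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(lig) < 1L) stop("Ligand table must have at least one row.", call. = FALSE)
  bad <- !is.finite(lig$a) | lig$a < 0
  if (any(bad)) stop("Efficacy `a` must be finite and >= 0 (offending: ",
                     paste(lig$id[bad], collapse = ", "), ").", call. = FALSE)
  bad <- !is.finite(lig$c) | lig$c <= 0
  if (any(bad)) stop("Potency `c` must be finite and > 0 (offending: ",
                     paste(lig$id[bad], collapse = ", "), ").", call. = FALSE)
  bad <- !is.finite(lig$n) | lig$n <= 0
  if (any(bad)) stop("Hill slope `n` must be finite and > 0 (offending: ",
                     paste(lig$id[bad], collapse = ", "), ").", call. = FALSE)
  lig
}

#' Define a mixture by its components and molar fractions
#'
#' A mixture is a ligand table plus a `fraction` column giving each
#' component's molar fraction of the total mixture concentration. Fractions
#' must be non-negative and sum to one (tolerance 1e-9).
#'
#' @param ligands Ligand table (see [as_ligand_tbl()]).
#' @param fractions Numeric vector of molar fractions, one per component.
#'   May be omitted if `ligands` already carries a `fraction` column.
#' @return A tibble of class `hillmix_mixture` with columns
#'   `id`, `a`, `c`, `n`, `fraction`.
#' @examples
#' mixture(
#'   data.frame(id = c("gen", "kae"), a = c(1.9, 0.6),
#'              c = c(1e-7, 2e-6), n = c(1.2, 1)),
#'   fractions = c(0.3, 0.7)
#' )
#' @export
mixture <- function(ligands, fractions = NULL) {
  lig <- as_ligand_tbl(ligands)
  if (is.null(fractions)) {
    if (is.null(lig[["fraction"]])) {
      stop("Supply `fractions` or a `fraction` column.", call. = FALSE)
    }
    fractions <- lig$fraction
  }
  fractions <- as.numeric(fractions)
  if (length(fractions) != nrow(lig)) {
    stop("Need one fraction per component (", nrow(lig), " components, ",
         length(fractions), " fractions).", call. = FALSE)
  }
  if (any(!is.finite(fractions) | fractions < 0)) {
    stop("Fractions must be finite and >= 0.", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("Fractions must sum to 1 (got ", format(sum(fractions), digits = 12),
         ").", call. = FALSE)
  }
  lig$fraction <- fractions
  class(lig) <- c("hillmix_mixture", class(tibble::tibble()))
  lig
}

as_mixture <- function(x) {
  if (inherits(x, "hillmix_mixture")) return(x)
  if (is.data.frame(x) && !is.null(x[["fraction"]])) return(mixture(x))
  if (is.data.frame(x) && nrow(x) == 1L) return(mixture(x, fractions = 1))
  stop("Cannot interpret `x` as a mixture; use `mixture()`.", call. = FALSE)
}
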