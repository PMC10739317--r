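#' Build a mixture exposure design
#'
#' A design couples a [mixture()] with the way it is dosed: a fixed-ratio
#' dilution series (`fixed_ratio`), a blend whose fractions equalise the
#' components' contributions at a benchmark effect level
#' (`equipotent_at_ECx`, e.g. EC10 or EC50), or a series added on top of a
#' constant dose of the reference agonist (`coexposure_with_reference`,
#' e.g. estradiol held at its EC50 while the mixture is diluted).
#'
#' @param mix A [mixture()] (for equipotent designs the fractions are
#'   recomputed from the requested effect level).
#' @param kind One of `"fixed_ratio"`, `"equipotent_at_ECx"`,
#'   `"coexposure_with_reference"`.
#' @param grid Total-concentration grid (molar, strictly increasing). If
#'   omitted, 8 log-spaced points spanning two decades either side of the
#'   mixture's CA EC50 (or the components' median EC50 when 50% is not
#'   reachable).
#' @param effect_level Benchmark level `X` (percent of reference span) for
#'   equipotent designs.
#' @param reference Reference ligand (e.g. E2) for co-exposure designs.
#' @param reference_dose Fixed molar dose of the reference, default its EC50.
#' @return A `mixture_design` object.
#' @examples
#' mx <- mixture(data.frame(a = c(1, 1), c = c(1e-9, 3e-9), n = c(1, 1)),
#'               fractions = c(0.5, 0.5))
#' mixture_design(mx)
#' @export
mixture_design <- function(mix,
                           kind = c("fixed_ratio", "equipotent_at_ECx",
                                    "coexposure_with_reference"),
                           grid = NULL, effect_level = NULL,
                           reference = NULL, reference_dose = NULL) {
  kind <- match.arg(kind)
  mix <- as_mixture(mix)
  if (kind == "equipotent_at_ECx") {
    if (is.null(effect_level)) {
      stop("Equipotent designs need an `effect_level`.", call. = FALSE)
    }
    mix <- equipotent_fractions(mix, effect_level)
  }
  if (kind == "coexposure_with_reference") {
    if (is.null(reference)) {
      stop("Co-exposure designs need a `reference` ligand.", call. = FALSE)
    }
    reference <- as_ligand_tbl(reference)
    if (nrow(reference) != 1L) stop("`reference` must be one ligand.", call. = FALSE)
    if (is.null(reference_dose)) reference_dose <- reference$c
    check_dose(reference_dose, "reference_dose")
  }
  if (is.null(grid)) {
    anchor <- tryCatch(ca_mixture_ecx(mix, 50),
                       error = function(e) stats::median(mix$c))
    grid <- anchor * 10^seq(-2, 2, length.out = 8)
  }
  grid <- as.numeric(grid)
  if (any(!is.finite(grid)) || any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing positive molar concentrations.",
         call. = FALSE)
  }
  structure(list(mix = mix, kind = kind, grid = grid,
                 effect_level = effect_level, reference = reference,
                 reference_dose = reference_dose),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("<mixture_design>", x$kind, "with", nrow(x$mix), "component(s)\n")
  cat("  grid:", length(x$grid), "points,",
      format(min(x$grid), digits = 3), "-", format(max(x$grid), digits = 3), "M\n")
  if (x$kind == "coexposure_with_reference") {
    cat("  reference", x$reference$id, "held at",
        format(x$reference_dose, digits = 3), "M\n")
  }
  print(tibble::as_tibble(x$mix))
  invisible(x)
}

# component dose matrix (k x m) for a design, including the fixed
# reference dose for co-exposure designs (extra row + ligand)
design_doses <- function(design) {
  doses <- outer(design$mix$fraction, design$grid)
  lig <- design$mix
  if (design$kind == "coexposure_with_reference") {
    doses <- rbind(doses, rep(design$reference_dose, length(design$grid)))
    lig <- dplyr::bind_rows(lig[, c("id", "a", "c", "n")],
                            design$reference[, c("id", "a", "c", "n")])
  }
  list(ligands = lig, doses = doses)
}

#' Predict a mixture curve under generic response addition (GRA)
#'
#' Evaluates the multi-ligand receptor-occupancy response at every total
#' concentration in the design grid, with component doses `x_i = f_i * T`
#' (plus the constant reference dose for co-exposure designs).
#'
#' @param design A [mixture_design()].
#' @param scale A [reference_scale()].
#' @return A tibble with `concentration`, `response`, `model = "GRA"`.
#' @export
predict_curve_gra <- function(design, scale = reference_scale()) {
  stopifnot(inherits(design, "mixture_design"))
  dd <- design_doses(design)
  tibble::tibble(concentration = design$grid,
                 response = gra_response(dd$ligands, dd$doses, scale),
                 model = "GRA")
}

#' Predict a mixture curve under concentration addition (CA)
#'
#' Concentration addition defines, for each effect level `X`, the mixture
#' concentration `(sum(f_i / ECx_i))^-1` that produces it. The curve is
#' obtained by inverting that map at each grid concentration: the effect
#' level solving `ECx_mix(X) = T` is found by bracketed root-finding on
#' `log(X)` (the map is strictly increasing), to ~1e-11 relative
#' tolerance. Levels above the weakest component's maximal effect are
#' unreachable under CA, so grid concentrations beyond that point are
#' capped at the ceiling and the curve is flagged as truncated: past its
#' ceiling CA has nothing more to predict, the model's documented failure
#' mode for blends containing partial agonists.
#'
#' Co-exposure designs are not meaningful under plain CA (the reference
#' dose is fixed, not co-diluted) and are refused.
#'
#' @inheritParams predict_curve_gra
#' @return A tibble with `concentration`, `response`, `model = "CA"`;
#'   attribute `truncation` records any capped tail.
#' @export
predict_curve_ca <- function(design, scale = reference_scale()) {
  stopifnot(inherits(design, "mixture_design"))
  if (design$kind == "coexposure_with_reference") {
    stop("CA prediction is undefined for co-exposure designs; use GRA.",
         call. = FALSE)
  }
  mix <- design$mix
  x_max <- 100 * min(mix$a) * (1 - 1e-12)     # highest CA-reachable level
  log_ecx <- function(lx) log(ca_mixture_ecx(mix, exp(lx)))
  lo <- log(1e-10)
  capped <- logical(length(design$grid))
  resp <- purrr::map_dbl(seq_along(design$grid), function(i) {
    tt <- design$grid[i]
    f <- function(lx) log_ecx(lx) - log(tt)
    if (f(log(x_max)) < 0) {                 # beyond the reachable plateau
      capped[i] <<- TRUE
      return(scale$y0 + span(scale) * x_max / 100)
    }
    if (f(lo) > 0) return(scale$y0)          # effectively zero effect
    r <- stats::uniroot(f, lower = lo, upper = log(x_max), tol = 1e-12,
                        maxiter = 300L)
    scale$y0 + span(scale) * exp(r$root) / 100
  })
  out <- tibble::tibble(concentration = design$grid, response = resp,
                        model = "CA")
  if (any(capped) && min(mix$a) < 1) {
    trunc <- tibble::tibble(
      ceiling_pct = 100 * min(mix$a),
      limiting = mix$id[which.min(mix$a)],
      n_capped = sum(capped))
    attr(out, "truncation") <- trunc
    warning("CA curve truncated: ", trunc$n_capped, " grid point(s) capped ",
            "at the ", signif(trunc$ceiling_pct, 4),
            "% ceiling set by component '", trunc$limiting, "'.",
            call. = FALSE)
  }
  out
}

#' Equipotent molar fractions at a benchmark effect level
#'
#' Returns the mixture whose components contribute equally at effect level
#' `X`: fractions proportional to each component's ECx,
#' `f_i = ECx_i / sum(ECx_j)` (the less potent a component, the more of it
#' the blend carries).
#'
#' @param ligands Ligand table; every component must reach `X`.
#' @param X Benchmark effect level (percent of reference span).
#' @return A [mixture()] with the computed `fraction` column.
#' @examples
#' equipotent_fractions(
#'   data.frame(id = c("A", "B"), a = c(1, 1), c = c(1e-9, 9e-9), n = c(1, 1)),
#'   X = 50)
#' @export
equipotent_fractions <- function(ligands, X) {
  lig <- as_ligand_tbl(ligands)
  ecx <- purrr::map_dbl(seq_len(nrow(lig)), function(i) {
    ecx_from_hill(lig[i, ], X)
  })
  mixture(lig[, c("id", "a", "c", "n")], fractions = ecx / sum(ecx))
}
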