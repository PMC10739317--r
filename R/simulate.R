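#' Plate layout for simulated reporter-gene assays
#'
#' Describes the dilution scheme a simulated plate uses: an 8-point
#' 1:10 serial dilution in triplicate by default, which is typical
#' CALUX practice, together with blank wells, a reference-agonist (E2)
#' standard series, QC wells dosed at the reference EC50, and the
#' noise level (7% multiplicative, matching triplicate luminescence
#' variability).
#'
#' @param n_points Number of dilution points.
#' @param top Top concentration (molar). If `NULL`, chosen per compound as
#'   `1000 * EC50` so the series spans the sigmoid.
#' @param step Dilution factor between consecutive points.
#' @param replicates Replicates per concentration (>= 3 for QC wells).
#' @param n_blanks Number of blank (vehicle) wells.
#' @param noise_fraction Noise as a fraction of signal.
#' @param noise_model `"multiplicative"` (sd proportional to signal) or
#'   `"additive"` (sd equal to `noise_fraction` of the reference span).
#' @return A `plate_design` list.
#' @export
plate_design <- function(n_points = 8L, top = NULL, step = 10,
                         replicates = 3L, n_blanks = 3L,
                         noise_fraction = 0.07,
                         noise_model = c("multiplicative", "additive")) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_points >= 2L, step > 1, replicates >= 1L, noise_fraction >= 0)
  structure(list(n_points = as.integer(n_points), top = top, step = step,
                 replicates = as.integer(replicates),
                 n_blanks = as.integer(n_blanks),
                 noise_fraction = noise_fraction, noise_model = noise_model),
            class = "plate_design")
}

design_grid <- function(design, anchor) {
  top <- design$top %||% (anchor * 1000)
  sort(top / design$step^(seq_len(design$n_points) - 1L))
}

apply_noise <- function(y_true, design, scale, noise_fraction = NULL) {
  nf <- noise_fraction %||% design$noise_fraction
  if (nf == 0) return(y_true)
  sdv <- if (design$noise_model == "multiplicative") nf * abs(y_true)
         else rep(nf * span(scale), length(y_true))
  pmax(0, y_true + stats::rnorm(length(y_true), 0, sdv))
}

#' Simulate a concentration-response curve on a plate
#'
#' Evaluates the true multi-ligand response for a compound or mixture on
#' the plate's dilution grid and perturbs each replicate with seeded
#' multiplicative Gaussian noise (sd = `noise_fraction` x signal),
#' truncated at zero response. The default noise of 7% reflects the
#' run-to-run variability of triplicate luminescence measurements.
#'
#' @param x A single [ligand()] or a [mixture()].
#' @param design A [plate_design()].
#' @param scale A [reference_scale()].
#' @param noise_fraction Overrides the design's noise fraction.
#' @param seed Integer seed (required whenever noise > 0).
#' @param sample_id Identifier written into the output.
#' @return A long tibble in the plate dialect: `sample_id`,
#'   `component_ids`, `concentration_M`, `replicate`, `response_pct`.
#' @examples
#' simulate_curve(ligand(1.8, 1e-9, 2, id = "gen"), seed = 7)
#' @export
simulate_curve <- function(x, design = plate_design(),
                           scale = reference_scale(), noise_fraction = NULL,
                           seed = NULL, sample_id = NULL) {
  nf <- noise_fraction %||% design$noise_fraction
  if (nf > 0 && is.null(seed)) {
    stop("A `seed` is required when simulating noisy plates.", call. = FALSE)
  }
  mix <- as_mixture(x)
  anchor <- tryCatch(ca_mixture_ecx(mix, 50),
                     error = function(e) stats::median(mix$c))
  grid <- design_grid(design, anchor)
  doses <- outer(mix$fraction, grid)
  y_true <- gra_response(mix[, c("id", "a", "c", "n")], doses, scale)
  reps <- design$replicates
  out <- tibble::tibble(
    sample_id = sample_id %||% paste(mix$id, collapse = "+"),
    component_ids = paste(mix$id, collapse = ";"),
    concentration_M = rep(grid, each = reps),
    replicate = rep(seq_len(reps), times = length(grid)),
    response_true = rep(y_true, each = reps))
  noisy <- if (nf > 0) {
    withr::with_seed(seed, apply_noise(out$response_true, design, scale, nf))
  } else {
    out$response_true
  }
  out$response_pct <- noisy
  out$response_true <- NULL
  out
}

#' Synthetic compound library for the estrogen-receptor assay
#'
#' Fifteen compounds spanning the classes the assay targets:
#' phytoestrogens (including the supra-agonists daidzein and genistein at
#' 180--200% efficacy and the partial agonist kaempferol at 60%),
#' plant-protection and food-contact-material chemicals with weak or no
#' agonism, and the reference agonist estradiol. EC50s and slopes are
#' SYNTHETIC placeholders drawn once from class-plausible ranges and
#' frozen here -- they are not measurements -- but every entry respects
#' the qualitative potency ordering the assay literature reports.
#'
#' @return A tibble with `id`, `class`, `a`, `c`, `n`, `provenance`.
#' @examples
#' fixture_library()
#' @export
fixture_library <- function() {
  tbl <- tibble::tribble(
    ~id,            ~class,             ~a,   ~c,      ~n,
    "E2",           "reference",        1.0,  5.0e-12, 1.0,
    "8-PN",         "phytoestrogen",    1.0,  8.0e-9,  1.1,
    "6-PN",         "phytoestrogen",    0.8,  6.0e-8,  0.9,
    "daidzein",     "phytoestrogen",    1.9,  4.0e-7,  1.3,
    "genistein",    "phytoestrogen",    2.0,  1.5e-7,  1.2,
    "kaempferol",   "phytoestrogen",    0.6,  2.0e-6,  1.0,
    "equol",        "phytoestrogen",    1.2,  2.5e-7,  1.1,
    "enterolactone","phytoestrogen",    0.5,  5.0e-6,  0.8,
    "BHT",          "FCM_related",      0.3,  1.0e-5,  0.7,
    "benzophenone", "FCM_related",      0.4,  8.0e-6,  1.0,
    "DEHP",         "FCM_related",      0.2,  2.0e-5,  0.6,
    "DBP",          "FCM_related",      0.25, 1.5e-5,  0.8,
    "DIBP",         "FCM_related",      0.2,  1.8e-5,  0.7,
    "BBP",          "FCM_related",      0.35, 9.0e-6,  0.9,
    "triadimenol",  "plant_protection", 0.15, 3.0e-5,  0.5)
  tbl$provenance <- "synthetic placeholder (class-plausible, not measured)"
  validate_ligands(tbl)
  stopifnot(all(tbl$a >= 0 & tbl$a <= 2.2),
            all(tbl$n >= 0.4 & tbl$n <= 5.5),
            all(tbl$c >= 1e-12 & tbl$c <= 1e-4))
  tbl
}

#' Default simulation scenario
#'
#' The study layout the generator emulates: single-compound curves for
#' the full library, twelve fixed-ratio mixtures of 2--5 compounds at
#' plausible food-like ratios (synthetic -- the real ratios are not
#' published), equipotent phytoestrogen blends at EC10 and EC50, and an
#' E2 co-exposure series with E2 held at its EC50.
#'
#' @param design A [plate_design()].
#' @return A `scenario` list understood by [simulate_study()].
#' @export
default_scenario <- function(design = plate_design()) {
  lib <- fixture_library()
  pick <- function(ids, fr) {
    mixture(lib[match(ids, lib$id), c("id", "class", "a", "c", "n")],
            fractions = fr / sum(fr))
  }
  mixtures <- list(
    mix01 = pick(c("daidzein", "genistein"), c(0.6, 0.4)),
    mix02 = pick(c("daidzein", "kaempferol"), c(0.5, 0.5)),
    mix03 = pick(c("genistein", "equol"), c(0.7, 0.3)),
    mix04 = pick(c("8-PN", "6-PN", "daidzein"), c(0.1, 0.2, 0.7)),
    mix05 = pick(c("daidzein", "genistein", "kaempferol"), c(0.4, 0.3, 0.3)),
    mix06 = pick(c("equol", "enterolactone", "kaempferol"), c(0.5, 0.3, 0.2)),
    mix07 = pick(c("BHT", "benzophenone", "DEHP"), c(0.3, 0.3, 0.4)),
    mix08 = pick(c("daidzein", "genistein", "equol", "kaempferol"),
                 c(0.35, 0.25, 0.25, 0.15)),
    mix09 = pick(c("DBP", "DIBP", "BBP", "DEHP"), c(0.25, 0.25, 0.25, 0.25)),
    mix10 = pick(c("8-PN", "daidzein", "kaempferol", "equol"),
                 c(0.05, 0.45, 0.3, 0.2)),
    mix11 = pick(c("daidzein", "genistein", "kaempferol", "equol",
                   "enterolactone"), c(0.3, 0.2, 0.2, 0.2, 0.1)),
    mix12 = pick(c("BHT", "benzophenone", "DBP", "BBP", "triadimenol"),
                 c(0.2, 0.2, 0.2, 0.2, 0.2)))
  phyto4 <- lib[match(c("8-PN", "daidzein", "kaempferol", "equol"), lib$id),
                c("id", "a", "c", "n")]
  structure(list(design = design,
                 singles = lib$id,
                 mixtures = mixtures,
                 equipotent = list(components = phyto4, levels = c(10, 50)),
                 coexposure = list(
                   components = phyto4[phyto4$id != "8-PN", ],
                   reference_id = "E2")),
            class = "hillmix_scenario")
}

#' Simulate a complete study
#'
#' Generates every plate the default analysis pipeline consumes: the E2
#' reference series, single-compound curves, twelve 2--5 component
#' fixed-ratio mixtures, equipotent benchmark blends, an E2 co-exposure
#' series and QC wells at the E2 EC50 -- together with the generating
#' ("truth") parameters for recovery testing. Fully reproducible from
#' `(scenario, seed)`.
#'
#' @param scenario A scenario from [default_scenario()].
#' @param seed Integer seed.
#' @param scale A [reference_scale()].
#' @return A list with `plates` (one long tibble in the plate dialect),
#'   `qc` (QC-well tibble), and `truth` (list of generating parameters).
#' @export
simulate_study <- function(scenario = default_scenario(), seed,
                           scale = reference_scale()) {
  stopifnot(inherits(scenario, "hillmix_scenario"))
  if (missing(seed)) stop("A `seed` is required.", call. = FALSE)
  lib <- fixture_library()
  des <- scenario$design
  plates <- list()
  sub_seed <- function(i) (seed * 1009L + i) %% .Machine$integer.max

  i <- 0L
  for (id in scenario$singles) {
    i <- i + 1L
    lig <- lib[lib$id == id, c("id", "a", "c", "n")]
    plates[[paste0("single_", id)]] <-
      simulate_curve(lig, des, scale, seed = sub_seed(i), sample_id = id)
  }
  for (nm in names(scenario$mixtures)) {
    i <- i + 1L
    plates[[nm]] <- simulate_curve(scenario$mixtures[[nm]], des, scale,
                                   seed = sub_seed(i), sample_id = nm)
  }
  for (lev in scenario$equipotent$levels) {
    i <- i + 1L
    eq <- equipotent_fractions(scenario$equipotent$components, lev)
    plates[[paste0("equipotent_EC", lev)]] <-
      simulate_curve(eq, des, scale, seed = sub_seed(i),
                     sample_id = paste0("equipotent_EC", lev))
  }
  # E2 held at its EC50 while the mixture is diluted over the plate grid
  i <- i + 1L
  ref <- lib[lib$id == scenario$coexposure$reference_id, c("id", "a", "c", "n")]
  co_mix <- mixture(scenario$coexposure$components,
                    fractions = rep(1 / nrow(scenario$coexposure$components),
                                    nrow(scenario$coexposure$components)))
  co_design <- mixture_design(co_mix, "coexposure_with_reference",
                              reference = ref, reference_dose = ref$c)
  co_true <- predict_curve_gra(co_design, scale)
  reps <- des$replicates
  co <- tibble::tibble(
    sample_id = "coexposure_E2",
    component_ids = paste(c(co_mix$id, ref$id), collapse = ";"),
    concentration_M = rep(co_true$concentration, each = reps),
    replicate = rep(seq_len(reps), times = nrow(co_true)),
    response_true = rep(co_true$response, each = reps))
  co$response_pct <- withr::with_seed(sub_seed(i),
    apply_noise(co$response_true, des, scale))
  co$response_true <- NULL
  plates[["coexposure_E2"]] <- co

  # QC wells: reference agonist at its EC50, triplicate
  i <- i + 1L
  e2 <- lib[lib$id == "E2", ]
  qc_true <- rep(hill_response(e2[, c("id", "a", "c", "n")], e2$c, scale), 3L)
  qc <- tibble::tibble(
    sample_id = "QC_E2_EC50",
    component_ids = "E2",
    concentration_M = e2$c,
    replicate = 1:3,
    response_pct = withr::with_seed(sub_seed(i),
                                    apply_noise(qc_true, des, scale)))

  truth <- list(scale = scale, library = lib,
                mixtures = scenario$mixtures,
                equipotent_levels = scenario$equipotent$levels,
                coexposure = list(mix = co_mix, reference = ref,
                                  reference_dose = ref$c),
                seed = seed)
  list(plates = dplyr::bind_rows(plates), qc = qc, truth = truth)
}
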