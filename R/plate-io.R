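#' Read a plate CSV
#'
#' The plate dialect is a long-format, comma-separated, UTF-8 file with
#' columns `sample_id`, `component_ids` (semicolon-separated),
#' `concentration_M` (molar, scientific notation), `replicate`, and either
#' `response_pct` (already normalised percent activity) or `response_rlu`
#' (raw luminescence). Raw files are normalised on read as
#' `100 * (signal - blank) / (E2max - blank)`, where the blank is the mean
#' of wells with `sample_id == "blank"` and `E2max` the largest mean
#' response of the `sample_id == "E2"` standard series.
#'
#' @param path File path.
#' @return A validated plate tibble (`sample_id`, `component_ids`,
#'   `concentration_M`, `replicate`, `response_pct`).
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "component_ids", "concentration_M", "replicate")
  problems <- character()
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(miss, collapse = ", ")))
  }
  has_pct <- "response_pct" %in% names(raw)
  has_rlu <- "response_rlu" %in% names(raw)
  if (!has_pct && !has_rlu) {
    problems <- c(problems, "need a `response_pct` or `response_rlu` column")
  }
  if (length(problems)) {
    stop("Plate file ", path, " is malformed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  if (!has_pct) {                        # raw luminescence: normalise
    blank_rows <- raw$sample_id == "blank"
    e2_rows <- raw$sample_id == "E2"
    if (!any(blank_rows) || !any(e2_rows)) {
      stop("Raw-luminescence plates need 'blank' wells and an 'E2' series ",
           "for normalisation.", call. = FALSE)
    }
    blank <- mean(raw$response_rlu[blank_rows])
    e2max <- raw[e2_rows, ] |>
      dplyr::group_by(.data$concentration_M) |>
      dplyr::summarise(m = mean(.data$response_rlu), .groups = "drop") |>
      dplyr::pull(.data$m) |> max()
    raw$response_pct <- 100 * (raw$response_rlu - blank) / (e2max - blank)
    raw$response_rlu <- NULL
  }

  out <- raw[!(raw$sample_id == "blank"), c(need, "response_pct")]
  bad_conc <- which(!is.finite(out$concentration_M) | out$concentration_M < 0)
  bad_resp <- which(!is.finite(out$response_pct))
  problems <- c(
    if (length(bad_conc)) paste0("negative or non-finite concentration_M in ",
                                 "row(s): ", paste(bad_conc, collapse = ", ")),
    if (length(bad_resp)) paste0("non-finite response in row(s): ",
                                 paste(bad_resp, collapse = ", ")))
  if (length(problems)) {
    stop("Plate file ", path, " is malformed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Write a plate tibble to CSV
#'
#' Inverse of [read_plate_csv()]: a write/read cycle returns the same
#' curves (concentrations round-trip through scientific notation at full
#' double precision).
#'
#' @param plate Plate tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  need <- c("sample_id", "component_ids", "concentration_M", "replicate",
            "response_pct")
  miss <- setdiff(need, names(plate))
  if (length(miss)) {
    stop("Plate tibble is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- plate[need]
  # full double precision so a write/read cycle reproduces the curves bit
  # for bit
  out$concentration_M <- sprintf("%.17g", out$concentration_M)
  out$response_pct <- sprintf("%.17g", out$response_pct)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a plate tibble into per-sample response curves
#'
#' @param plate Plate tibble.
#' @return Named list of tibbles with `concentration` and `response`
#'   columns (replicates as rows), ready for [fit_hill()].
#' @export
as_curves <- function(plate) {
  plate |>
    dplyr::transmute(sample_id = .data$sample_id,
                     concentration = .data$concentration_M,
                     response = .data$response_pct) |>
    (\(d) split(d[c("concentration", "response")], d$sample_id))()
}

#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: where the data come from
#' (a synthetic scenario or observed plate files), which mixture models
#' to evaluate, the Monte-Carlo settings, and where results go. The seed
#' is mandatory: every stochastic step derives its stream from it, and
#' rerunning the same configuration reproduces every number. The
#' configuration round-trips losslessly through JSON.
#'
#' @param mode `"synthetic"` (simulate the default scenario) or
#'   `"observed"` (read plate CSVs from `input_paths`).
#' @param input_paths Character vector of plate CSV paths (observed mode).
#' @param models Models to evaluate: subset of `c("CA", "GRA")`.
#' @param n_sims Monte-Carlo draws per envelope.
#' @param seed Integer seed (required).
#' @param uncertainty_rel Relative half-width of the uniform parameter
#'   uncertainty used for envelopes.
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "observed"),
                       input_paths = character(), models = c("CA", "GRA"),
                       n_sims = 2000, seed, uncertainty_rel = 0.1,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  models <- match.arg(models, c("CA", "GRA"), several.ok = TRUE)
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  if (mode == "observed" && length(input_paths) == 0L) {
    stop("Observed mode needs `input_paths`.", call. = FALSE)
  }
  structure(list(mode = mode, input_paths = input_paths, models = models,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 uncertainty_rel = uncertainty_rel, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(mode = x$mode, input_paths = x$input_paths %||% character(),
             models = x$models, n_sims = x$n_sims, seed = x$seed,
             uncertainty_rel = x$uncertainty_rel, out_dir = x$out_dir)
}

#' Run the full mixture-analysis pipeline
#'
#' Executes every stage on either synthetic or observed plates:
#' reference (E2) fit defining the plate scale, single-compound Hill
#' fits, CA and GRA mixture predictions on each observed mixture's grid,
#' Monte-Carlo 95% envelopes, additivity verdicts, and CA-vs-GRA model
#' comparison. When `out_dir` is set, per-mixture envelope/verdict CSVs,
#' a JSON verdict summary and a run log (seed, configuration hash,
#' package version) are written.
#'
#' @param config A [run_config()].
#' @return Invisibly, a result bundle: `scale`, `single_fits`,
#'   `mixtures` (per-mixture list with predictions, envelopes, verdicts,
#'   comparison), and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  result <- tryCatch({
    if (config$mode == "synthetic") {
      study <- simulate_study(seed = config$seed)
      plates <- study$plates
      truth <- study$truth
    } else {
      plates <- dplyr::bind_rows(lapply(config$input_paths, read_plate_csv))
      truth <- NULL
    }
    curves <- as_curves(plates)

    stage <- "reference_fit"
    scale <- reference_scale()
    e2_ref <- NULL
    if ("E2" %in% names(curves)) {
      e2_ref <- fit_e2_reference(curves[["E2"]])
      scale <- e2_ref$scale
    }

    stage <- "single_fits"
    mix_ids <- grep("^mix[0-9]+$", names(curves), value = TRUE)
    single_ids <- setdiff(names(curves),
                          c(mix_ids, "E2",
                            grep("^(equipotent|coexposure|QC)", names(curves),
                                 value = TRUE)))
    single_fits <- lapply(curves[single_ids], fit_hill, scale = scale)

    stage <- "mixtures"
    lib <- if (!is.null(truth)) truth$library else NULL
    mix_results <- lapply(mix_ids, function(nm) {
      obs <- curves[[nm]]
      ids <- strsplit(plates$component_ids[plates$sample_id == nm][1], ";")[[1]]
      comp <- if (!is.null(lib)) {
        truth$mixtures[[nm]]
      } else {
        # observed mode: component parameters come from the single fits
        params <- dplyr::bind_rows(lapply(single_fits[ids],
                                          function(f) f$params))
        params$id <- ids
        mixture(params[, c("id", "a", "c", "n")],
                fractions = rep(1 / length(ids), length(ids)))
      }
      grid <- sort(unique(obs$concentration))
      des <- mixture_design(comp, "fixed_ratio", grid = grid)
      gra <- predict_curve_gra(des, scale)
      ca <- withCallingHandlers(predict_curve_ca(des, scale),
                                warning = function(w) invokeRestart("muffleWarning"))
      unc <- uncertainty_uniform(comp, rel = config$uncertainty_rel)
      envs <- verdicts <- list()
      for (mdl in config$models) {
        env <- mc_envelope(des, unc, model = mdl,
                           n_sims = max(config$n_sims, 1000),
                           seed = config$seed + match(nm, mix_ids),
                           scale = scale)
        envs[[mdl]] <- env
        verdicts[[mdl]] <- additivity_test(obs, env)
      }
      cmp <- if (all(c("CA", "GRA") %in% config$models)) {
        compare_models(obs, ca, gra)
      }
      list(id = nm, design = des, observed = obs, ca = ca, gra = gra,
           envelopes = envs, verdicts = verdicts, comparison = cmp)
    })
    names(mix_results) <- mix_ids

    stage <- "report"
    log <- tibble::tibble(
      stage = "run", seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      package_version = as.character(utils::packageVersion("hillmix")),
      n_mixtures = length(mix_results))
    bundle <- list(scale = scale, reference = e2_ref,
                   single_fits = single_fits, mixtures = mix_results,
                   log = log)
    if (!is.null(config$out_dir)) write_bundle(bundle, config)
    bundle
  }, error = function(e) {
    stop("Pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  verdict_rows <- purrr::imap_dfr(bundle$mixtures, function(mx, nm) {
    purrr::imap_dfr(mx$verdicts, function(v, mdl) {
      dplyr::mutate(glance(v), mixture = nm, .before = 1)
    })
  })
  jsonlite::write_json(
    list(seed = config$seed, config_hash = bundle$log$config_hash,
         verdicts = verdict_rows),
    file.path(config$out_dir, "verdicts.json"),
    auto_unbox = TRUE, digits = NA)
  for (nm in names(bundle$mixtures)) {
    mx <- bundle$mixtures[[nm]]
    for (mdl in names(mx$envelopes)) {
      readr::write_csv(mx$envelopes[[mdl]]$band,
                       file.path(config$out_dir,
                                 paste0(nm, "_envelope_", mdl, ".csv")),
                       progress = FALSE)
      readr::write_csv(tidy(mx$verdicts[[mdl]]),
                       file.path(config$out_dir,
                                 paste0(nm, "_verdict_", mdl, ".csv")),
                       progress = FALSE)
    }
    if (!is.null(mx$comparison)) {
      readr::write_csv(mx$comparison,
                       file.path(config$out_dir, paste0(nm, "_models.csv")),
                       progress = FALSE)
    }
  }
  readr::write_csv(bundle$log, file.path(config$out_dir, "run_log.csv"),
                   progress = FALSE)
  invisible(NULL)
}
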