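#' Pooled cohort correction ratios from many subjects
#'
#' Binds all subjects' discrete samples and arterial panels and computes
#' population-provenance ratios with [compute_ratios()].
#'
#' @param bundles List of subject bundles ([generate_subject()] or
#'   [read_subject()]).
#' @return A [ratio_set()] with provenance `"population"`.
#' @export
cohort_ratios <- function(bundles) {
  samples <- dplyr::bind_rows(purrr::map(bundles, "samples"))
  panels <- purrr::flatten(purrr::map(bundles, "panels"))
  compute_ratios(samples, panels, provenance = "population")
}

#' Individual plasma free-leucine input function for one subject
#'
#' The full blood pipeline: decay-correct the online detector curve to
#' injection, cross-calibrate and delay-align it against the discrete
#' gamma-counted samples, convert whole blood to plasma free tracer with
#' the cohort ratios, and resample onto the canonical analysis grid.
#'
#' @param bundle A subject bundle with `online`, `samples` and
#'   `injection_marker_min`.
#' @param ratios A [ratio_set()]; defaults to the subject's own samples
#'   and arterial panel.
#' @param grid Analysis grid; default [pbif_grid()].
#' @param align_delay Passed to [calibrate_online_curve()].
#' @return A plasma-free [sampled_curve()] on `grid`.
#' @export
subject_input_function <- function(bundle, ratios = NULL,
                                   grid = pbif_grid(), align_delay = TRUE) {
  ratios <- ratios %||% compute_ratios(bundle$samples, bundle$panels)
  online_c <- decay_correct(bundle$online, ref_time_min = 0)
  cal <- calibrate_online_curve(
    online_c, bundle$samples,
    injection_start_min = bundle$injection_marker_min %||% 0,
    align_delay = align_delay
  )
  cp <- to_plasma_free(cal, ratios)
  sampled_curve(grid, pmax(curve_interp(cp, grid), 0),
                role = "plasma_free")
}

#' Fit every region of one subject
#'
#' Fits the compartmental model to each regional TAC against the supplied
#' (or subject-derived) input function and returns one tidy row per region
#' including the derived lambda, Kcplx, PSR and the 20-60 min SUV.
#'
#' @param bundle A subject bundle.
#' @param cp Plasma-free input [sampled_curve()]; default
#'   [subject_input_function()] from the bundle's own blood data.
#' @param ratios A [ratio_set()] supplying the unlabelled leucine
#'   concentration (and the input-function conversion when `cp` is
#'   derived here).
#' @param suv_window SUV averaging window, min.
#' @param ... Passed to [fit_rate_constants()].
#' @return Tibble of [region_result()] rows; the `leu_fit` objects are in
#'   `attr(, "fits")`.
#' @export
fit_subject <- function(bundle, cp = NULL, ratios = NULL,
                        suv_window = c(20, 60), ...) {
  ratios <- ratios %||% compute_ratios(bundle$samples, bundle$panels)
  cp <- cp %||% subject_input_function(bundle, ratios)
  sch <- bundle$schedule
  regions <- unique(bundle$tacs$region)
  fits <- list()
  rows <- purrr::map_dfr(regions, function(rg) {
    act <- bundle$tacs$activity_Bq_per_ml[bundle$tacs$region == rg]
    fit <- fit_rate_constants(act, sch, cp,
                              leu = ratios$leucine_conc, ...)
    fits[[rg]] <<- fit
    sv <- suv(window_mean(act, sch, suv_window), bundle$meta)
    region_result(bundle$subject, rg, arm = bundle$arm, fit = fit,
                  suv_value = sv)
  })
  attr(rows, "fits") <- fits
  rows
}

# ---------------------------------------------------------------------
# Run configuration (YAML) and end-to-end runs
# ---------------------------------------------------------------------

#' Read, validate and write a run configuration
#'
#' A single YAML file drives end-to-end runs. Top-level keys: `version`
#' (schema version, currently 1), `mode` (`"individual_aif"` or `"pbif"`),
#' `inputs` (`subjects_dir`, optionally `pbif_template`), `fitting`
#' (`weighting`, `vb`, `align_delay`), `pbif` (`window`), `output_dir`,
#' `simulate` (`n_subjects`, `arm`, `seed`, `noise`, and optional
#' [cohort_spec()] overrides) and `seed`. Every under-specified convention of the method
#' (weighting, scaling window, delay alignment) is an explicit setting
#' here. Configurations round-trip read -> write -> read identically.
#'
#' @param path YAML file path.
#' @param config A run-config list (from [read_run_config()] or built in
#'   code).
#' @return The validated config list (reader) or `path` (writer).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist.", path), call. = FALSE)
  }
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(validate_run_config(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  defaults <- list(
    version = 1L,
    mode = "individual_aif",
    inputs = list(),
    fitting = list(weighting = "duration_decay", vb = 0,
                   align_delay = TRUE),
    pbif = list(window = c(10, 60)),
    output_dir = "leupet_out",
    seed = 1L,
    simulate = list()
  )
  config <- utils::modifyList(defaults, config)
  if (!config$mode %in% c("individual_aif", "pbif")) {
    stop("mode must be 'individual_aif' or 'pbif'.", call. = FALSE)
  }
  if (!identical(as.integer(config$version), 1L)) {
    stop("unsupported config schema version: ", config$version,
         call. = FALSE)
  }
  config
}

run_manifest <- function(config, inputs = character(), extra = list()) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  c(list(
    package = "leupet",
    version = as.character(utils::packageVersion("leupet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = hashes
  ), extra)
}

subject_dirs <- function(config) {
  root <- config$inputs$subjects_dir
  if (is.null(root) || !dir.exists(root)) {
    stop("inputs$subjects_dir is missing or does not exist: ",
         root %||% "<unset>", call. = FALSE)
  }
  dirs <- list.dirs(root, recursive = FALSE)
  if (!length(dirs)) stop("no subject directories under ", root,
                          call. = FALSE)
  sort(dirs)
}

#' Simulate a synthetic study onto disk
#'
#' Thin configuration wrapper over the generator: builds a [cohort_spec()]
#' from `config$simulate` (keys `n`, `arm`, `seed`, `noise` =
#' `"default"`/`"none"`, plus any cohort_spec override), writes one
#' directory per subject under `output_dir/subjects/`, and a manifest.
#' Same-seed reruns are byte-identical (modulo the manifest timestamp).
#'
#' @param config Run config (list or YAML path).
#' @return Tibble of subject ids and directories, invisibly.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  sim <- config$simulate
  # YAML 1.1 parses a bare `n:` key as a boolean, so the canonical config
  # key is `n_subjects`; plain `n` still works for in-code configs.
  n <- sim$n_subjects %||% sim$n %||% 6L
  arm <- sim$arm %||% "baseline"
  spec_args <- sim[setdiff(names(sim),
                           c("n", "n_subjects", "arm", "noise"))]
  spec_args$seed <- spec_args$seed %||% config$seed
  spec <- do.call(cohort_spec, spec_args)
  if (identical(sim$noise, "none")) spec <- noise_free(spec)
  out_root <- file.path(config$output_dir, "subjects")
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    b <- generate_subject(spec, i, arm)
    d <- file.path(out_root, b$subject)
    write_subject(b, d)
    tibble::tibble(subject = b$subject, arm = arm, dir = d)
  })
  jsonlite::write_json(run_manifest(config),
                       file.path(config$output_dir,
                                 "simulate_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rows)
}

#' Fit a study end-to-end from files
#'
#' Reads every subject directory, builds the input function per the
#' configured mode (individual online-blood AIF, or PBIF scaled by each
#' subject's image-derived/whole-blood curve), fits all regions, and
#' writes `fits.tsv` plus a run manifest to `output_dir`. Ratios and
#' unlabelled leucine are pooled over the cohort (population provenance)
#' in `pbif` mode and taken per subject in `individual_aif` mode.
#'
#' @param config Run config (list or YAML path).
#' @return The fit-result tibble, invisibly.
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dirs <- subject_dirs(config)
  bundles <- purrr::map(dirs, read_subject)
  fit_opts <- list(weighting = config$fitting$weighting,
                   vb = config$fitting$vb)

  if (config$mode == "individual_aif") {
    results <- purrr::map_dfr(bundles, function(b) {
      ratios <- compute_ratios(b$samples, b$panels)
      cp <- subject_input_function(
        b, ratios, align_delay = isTRUE(config$fitting$align_delay))
      do.call(fit_subject, c(list(b, cp = cp, ratios = ratios), fit_opts))
    })
  } else {
    ratios <- cohort_ratios(bundles)
    template <- if (!is.null(config$inputs$pbif_template)) {
      read_pbif(config$inputs$pbif_template)
    } else {
      aifs <- purrr::map(bundles, function(b) {
        subject_input_function(
          b, ratios, align_delay = isTRUE(config$fitting$align_delay))
      })
      names(aifs) <- purrr::map_chr(bundles, "subject")
      build_pbif(aifs)
    }
    window <- as.numeric(config$pbif$window)
    results <- purrr::map_dfr(bundles, function(b) {
      idif <- subject_idif(b, config)
      cp <- scale_pbif(template, idif, ratios, window = window)
      do.call(fit_subject, c(list(b, cp = cp, ratios = ratios), fit_opts))
    })
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_fit_table(results, file.path(config$output_dir, "fits.tsv"))
  inputs <- unlist(purrr::map(dirs, function(d) {
    list.files(d, full.names = TRUE)
  }))
  jsonlite::write_json(run_manifest(config, inputs),
                       file.path(config$output_dir, "fit_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

# The subject's whole-blood curve for PBIF scaling: an idif.tsv file
# (image-derived, from extract_idif) if the subject directory has one,
# else the calibrated online curve; both are whole-blood in Bq/ml,
# decay-corrected.
subject_idif <- function(bundle, config) {
  dir <- attr(bundle, "dir")
  if (!is.null(dir) && file.exists(file.path(dir, "idif.tsv"))) {
    return(read_curve(file.path(dir, "idif.tsv")))
  }
  calibrate_online_curve(
    decay_correct(bundle$online, ref_time_min = 0),
    bundle$samples,
    injection_start_min = bundle$injection_marker_min %||% 0,
    align_delay = isTRUE(config$fitting$align_delay)
  )
}

#' Study-level report tables from fit outputs
#'
#' Reads `fits.tsv` from `output_dir` (or `inputs$fits`), and writes
#' `summary.tsv` (mean/SD/n of PSR, Kcplx and SUV by arm x region),
#' `inhibition.tsv` (percent inhibition of group-mean Kcplx and PSR per
#' region when both arms are present), and, when `inputs$fits_pbif` names
#' a second fit table, an input-function agreement report
#' (`agreement.tsv`/`.json`).
#'
#' @param config Run config (list or YAML path).
#' @return Named list of the tables written, invisibly.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  fits_path <- config$inputs$fits %||%
    file.path(config$output_dir, "fits.tsv")
  fits <- read_fit_table(fits_path)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  long <- tidyr::pivot_longer(fits, dplyr::all_of(c("PSR", "Kcplx", "suv")),
                              names_to = "measure", values_to = "value")
  out$summary <- summarize_groups(long, "value",
                                  by = c("measure", "arm", "region"))
  readr::write_tsv(out$summary, file.path(config$output_dir, "summary.tsv"))

  arms <- unique(fits$arm)
  if (all(c("baseline", "anisomycin") %in% arms)) {
    gm <- summarize_groups(long, "value", by = c("measure", "arm", "region"))
    wide <- tidyr::pivot_wider(gm[, c("measure", "arm", "region", "mean")],
                               names_from = "arm", values_from = "mean")
    inh <- wide |>
      dplyr::filter(.data$measure %in% c("PSR", "Kcplx")) |>
      dplyr::mutate(percent_inhibition = percent_inhibition(
        .data$baseline, .data$anisomycin)) |>
      dplyr::arrange(.data$measure, .data$region)
    out$inhibition <- inh
    readr::write_tsv(inh, file.path(config$output_dir, "inhibition.tsv"))
  }

  if (!is.null(config$inputs$fits_pbif)) {
    pbif_fits <- read_fit_table(config$inputs$fits_pbif)
    agree <- compare_if_methods(
      dplyr::rename(fits[, c("subject", "region", "PSR")], value = "PSR"),
      dplyr::rename(pbif_fits[, c("subject", "region", "PSR")],
                    value = "PSR")
    )
    out$agreement <- agree
    write_agreement(agree,
                    path_tsv = file.path(config$output_dir,
                                         "agreement.tsv"),
                    path_json = file.path(config$output_dir,
                                          "agreement.json"))
  }
  jsonlite::write_json(run_manifest(config, fits_path),
                       file.path(config$output_dir,
                                 "report_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
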