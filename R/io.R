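# Plain-text file dialects shared by the generator (writer) and the
# pipeline (reader), so synthetic fixtures and real exports are
# interchangeable. All tables are TSV; curves carry a one-line '#' JSON
# header recording role and decay-correction state.

curve_header <- function(curve) {
  paste0("# ", jsonlite::toJSON(list(
    role = curve_role(curve),
    decay_corrected = is_decay_corrected(curve),
    ref_time_min = attr(curve, "ref_time_min") %||% 0,
    units = attr(curve, "units") %||% "Bq/ml"
  ), auto_unbox = TRUE))
}

#' Write / read a sampled curve as TSV
#'
#' Two columns `time_min`, `value`, preceded by a `#` JSON header with the
#' curve's role, units and decay-correction state.
#'
#' @param curve A [sampled_curve()].
#' @param path File path.
#' @return The path (writer) or the curve (reader).
#' @export
write_curve <- function(curve, path) {
  curve <- as_leu_curve(curve)
  writeLines(c(curve_header(curve), "time_min\tvalue",
               sprintf("%.10g\t%.10g", curve$time_min, curve$value)), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- if (any(is_hdr)) {
    jsonlite::fromJSON(sub("^#\\s*", "", lines[which(is_hdr)[1]]))
  } else {
    list(role = "tissue", decay_corrected = TRUE, ref_time_min = 0,
         units = "Bq/ml")
  }
  tab <- utils::read.delim(text = lines[!is_hdr])
  sampled_curve(tab$time_min, tab$value, role = meta$role,
                decay_corrected = meta$decay_corrected,
                ref_time_min = meta$ref_time_min, units = meta$units)
}

#' Write / read a regional TAC table
#'
#' Columns `frame_start_min`, `frame_end_min`, `region`,
#' `activity_Bq_per_ml` (one row per region x frame).
#'
#' @param tacs Tibble in the above layout (extra columns are kept).
#' @param path File path.
#' @return The path (writer) or the table (reader).
#' @export
write_tacs <- function(tacs, path) {
  need <- c("frame_start_min", "frame_end_min", "region",
            "activity_Bq_per_ml")
  if (!all(need %in% names(tacs))) {
    stop("TAC table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(tacs[, union(need, names(tacs))], path)
  invisible(path)
}

#' @rdname write_tacs
#' @export
read_tacs <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!nrow(tab)) {
    stop(sprintf("TAC file '%s' is empty.", path), call. = FALSE)
  }
  tab
}

#' Write / read a discrete blood-sample table
#'
#' Columns `time_min`, `whole_blood_Bq_per_ml`, `plasma_Bq_per_ml`,
#' `plasma_free_Bq_per_ml`, `site`.
#'
#' @param samples A [blood_samples()] table.
#' @param path File path.
#' @return The path (writer) or the table (reader).
#' @export
write_blood <- function(samples, path) {
  out <- tibble::tibble(
    time_min = samples$time_min,
    whole_blood_Bq_per_ml = samples$whole_blood,
    plasma_Bq_per_ml = samples$plasma,
    plasma_free_Bq_per_ml = samples$plasma_free,
    site = samples$site
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_blood
#' @export
read_blood <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  blood_samples(tab$time_min, tab$whole_blood_Bq_per_ml,
                tab$plasma_Bq_per_ml, tab$plasma_free_Bq_per_ml, tab$site)
}

#' Write / read amino-acid panels
#'
#' One row per panel; one column per LNAA (nmol/ml) plus `site` and
#' `age_months`.
#'
#' @param panels List of [amino_acid_panel()] rows or a bound tibble.
#' @param path File path.
#' @return The path (writer) or a tibble of panels (reader).
#' @export
write_panels <- function(panels, path) {
  if (!is.data.frame(panels)) panels <- dplyr::bind_rows(panels)
  readr::write_tsv(panels, path)
  invisible(path)
}

#' @rdname write_panels
#' @export
read_panels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  class(tab) <- c("leu_panel", class(tab))
  tab
}

#' Write a synthetic subject bundle to a directory
#'
#' Emits the file dialects the pipeline reads: `tacs.tsv`, `blood.tsv`,
#' `online.tsv` (detector units, not decay-corrected), `aif_true.tsv`,
#' `panels.tsv`, `meta.json` (weight, dose, arm, injection marker) and
#' `truth.tsv` (generator ground truth, for validation only).
#'
#' @param bundle A [generate_subject()] bundle.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tacs(bundle$tacs, file.path(dir, "tacs.tsv"))
  write_blood(bundle$samples, file.path(dir, "blood.tsv"))
  write_curve(bundle$online, file.path(dir, "online.tsv"))
  write_curve(bundle$aif, file.path(dir, "aif_true.tsv"))
  write_panels(bundle$panels, file.path(dir, "panels.tsv"))
  meta <- c(as.list(bundle$meta),
            list(subject = bundle$subject, arm = bundle$arm,
                 injection_marker_min = bundle$injection_marker_min))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(bundle$truth$regions, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a subject directory written by [write_subject()]
#'
#' @param dir Subject directory.
#' @return A list with the same elements the pipeline needs: `subject`,
#'   `arm`, `tacs`, `samples`, `online`, `panels`, `schedule`, `meta`,
#'   `injection_marker_min`, and `truth` when present.
#' @export
read_subject <- function(dir) {
  need <- file.path(dir, c("tacs.tsv", "blood.tsv", "online.tsv",
                           "panels.tsv", "meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing subject input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tacs <- read_tacs(file.path(dir, "tacs.tsv"))
  meta_json <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  frames <- dplyr::distinct(tacs[, c("frame_start_min", "frame_end_min")])
  frames <- dplyr::arrange(frames, .data$frame_start_min)
  panels <- read_panels(file.path(dir, "panels.tsv"))
  out <- list(
    subject = meta_json$subject %||% basename(dir),
    arm = meta_json$arm %||% "baseline",
    tacs = tacs,
    samples = read_blood(file.path(dir, "blood.tsv")),
    online = read_curve(file.path(dir, "online.tsv")),
    panels = split(panels, seq_len(nrow(panels))),
    schedule = frame_schedule(frames$frame_start_min, frames$frame_end_min),
    injection_marker_min = meta_json$injection_marker_min %||% 0,
    meta = subject_meta(meta_json$body_weight_g,
                        meta_json$injected_dose_MBq)
  )
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    out$truth <- list(regions = readr::read_tsv(truth_path,
                                                show_col_types = FALSE))
  }
  aif_path <- file.path(dir, "aif_true.tsv")
  if (file.exists(aif_path)) out$aif <- read_curve(aif_path)
  class(out) <- "leu_subject"
  attr(out, "dir") <- dir
  out
}

#' Write / read a fit-result table
#'
#' One row per subject x region: `subject`, `region`, `genotype`,
#' `age_months`, `arm`, `K1`, `k2`, `k3`, `lambda`, `Kcplx`, `PSR`,
#' `wrss`, `converged`, `suv`.
#'
#' @param results Tibble of bound [region_result()] rows.
#' @param path File path.
#' @return The path (writer) or the table (reader).
#' @export
write_fit_table <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("fit table '%s' does not exist.", path), call. = FALSE)
  }
  readr::read_tsv(path, show_col_types = FALSE)
}
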