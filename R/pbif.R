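#' Canonical PBIF time grid
#'
#' 0.05-min spacing to 2 min (dense across the bolus peak), then 0.5-min
#' spacing to 60 min.
#'
#' @return Numeric vector of times in minutes.
#' @export
pbif_grid <- function() {
  c(seq(0, 2, by = 0.05), seq(2.5, 60, by = 0.5))
}

#' Build a population-based input function template from donor AIFs
#'
#' Each donor arterial input function is resampled to the canonical grid,
#' normalized to unit 0-60 min trapezoidal area (so detector gain and
#' injected dose drop out), and the donors are averaged pointwise; the
#' average is renormalized to unit area. Donor-order and donor-gain
#' invariance follow by construction.
#'
#' @param aifs A list of plasma-free [sampled_curve()] donors (named list
#'   names are used in error messages), each covering 0-60 min with
#'   positive area.
#' @param grid Canonical time grid; default [pbif_grid()].
#' @param normalization `"auc"` (default) or `"dose"`; the latter divides
#'   each donor by `dose_per_g` taken from `attr(aif, "dose_per_g")`.
#' @return A tibble of class `leu_pbif` (columns `time_min`, `value`) with
#'   unit area, plus attributes `n_donors` and `donor_auc`.
#' @export
build_pbif <- function(aifs, grid = pbif_grid(),
                       normalization = c("auc", "dose")) {
  normalization <- match.arg(normalization)
  if (!is.list(aifs) || length(aifs) < 2L) {
    stop("at least 2 donor AIFs are required.", call. = FALSE)
  }
  nm <- names(aifs) %||% paste0("donor", seq_along(aifs))
  nm[nm == ""] <- paste0("donor", which(nm == ""))
  aucs <- numeric(length(aifs))
  mat <- matrix(NA_real_, nrow = length(grid), ncol = length(aifs))
  for (i in seq_along(aifs)) {
    aif <- as_leu_curve(aifs[[i]], role = "plasma_free")
    if (max(aif$time_min) < max(grid) - 1e-9) {
      stop(sprintf("donor '%s' does not cover the canonical grid (ends %.3g min).",
                   nm[i], max(aif$time_min)), call. = FALSE)
    }
    auc <- curve_auc(aif, 0, max(grid))
    if (!is.finite(auc) || auc <= 0) {
      stop(sprintf("donor '%s' has non-positive 0-60 min area.", nm[i]),
           call. = FALSE)
    }
    aucs[i] <- auc
    denom <- if (normalization == "auc") auc else {
      d <- attr(aifs[[i]], "dose_per_g")
      if (is.null(d) || !is.finite(d) || d <= 0) {
        stop(sprintf("donor '%s' lacks a positive `dose_per_g` attribute.",
                     nm[i]), call. = FALSE)
      }
      d
    }
    mat[, i] <- curve_interp(aif, grid) / denom
  }
  avg <- rowMeans(mat)
  avg <- pmax(avg, 0)
  template <- sampled_curve(grid, avg, role = "plasma_free")
  template <- curve_update(template,
                           value = template$value / curve_auc(template))
  class(template) <- unique(c("leu_pbif", class(template)))
  attr(template, "n_donors") <- length(aifs)
  attr(template, "donor_auc") <- stats::setNames(aucs, nm)
  attr(template, "normalization") <- normalization
  template
}

#' Scale a PBIF template to a subject using an image-derived blood curve
#'
#' The subject's plasma free-leucine input is `template(t) * S` with
#' `S = AUC_window(idif * plasma_over_wb * free_fraction) /
#' AUC_window(template)`. The default 10-60 min window avoids early
#' left-ventricle spill-in and bolus-shape mismatch, and matches the
#' late-time area that the trapping estimate actually integrates.
#'
#' @param template A [build_pbif()] template (unit area, plasma-free).
#' @param idif Image-derived whole-blood [sampled_curve()] in Bq/ml,
#'   decay-corrected (see [extract_idif()]).
#' @param ratios A [ratio_set()] giving the plasma/whole-blood and
#'   free-fraction conversion.
#' @param window Numeric `c(t0, t1)` scaling window in minutes, within both
#'   curves' support.
#' @return The subject plasma-free input as a [sampled_curve()], with
#'   attribute `pbif_scale` = S.
#' @export
scale_pbif <- function(template, idif, ratios, window = c(10, 60)) {
  template <- as_leu_curve(template, role = "plasma_free")
  idif <- as_leu_curve(idif, role = "whole_blood")
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("`window` must be c(t0, t1) with t1 > t0.", call. = FALSE)
  }
  if (window[2] > max(idif$time_min) + 1e-6 ||
      window[2] > max(template$time_min) + 1e-6) {
    stop("scaling window extends beyond a curve's support.", call. = FALSE)
  }
  cp_like <- curve_update(idif,
    value = idif$value * ratios$plasma_over_wb * ratios$free_fraction,
    role = "plasma_free")
  num <- curve_auc(cp_like, window[1], window[2])
  den <- curve_auc(template, window[1], window[2])
  if (!is.finite(num) || num <= 0 || !is.finite(den) || den <= 0) {
    stop("non-positive window area in the IDIF or the template.",
         call. = FALSE)
  }
  s <- num / den
  out <- curve_update(template, value = template$value * s)
  class(out) <- setdiff(class(out), "leu_pbif")
  attr(out, "pbif_scale") <- s
  out
}

#' Write / read a PBIF template as TSV with a JSON provenance header
#'
#' The file starts with `#` comment lines holding a JSON provenance record
#' (donor count, normalization, donor areas), followed by a
#' `time_min<TAB>value` table.
#'
#' @param template A [build_pbif()] template.
#' @param path Output file path.
#' @return `path`, invisibly (writer); the template (reader).
#' @export
write_pbif <- function(template, path) {
  meta <- list(
    n_donors = attr(template, "n_donors"),
    normalization = attr(template, "normalization"),
    donor_auc = as.list(attr(template, "donor_auc"))
  )
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  writeLines(c(hdr, "time_min\tvalue",
               sprintf("%.10g\t%.10g", template$time_min, template$value)),
             path)
  invisible(path)
}

#' @rdname write_pbif
#' @export
read_pbif <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  template <- sampled_curve(tab$time_min, tab$value, role = "plasma_free")
  class(template) <- unique(c("leu_pbif", class(template)))
  if (length(hdr)) {
    meta <- jsonlite::fromJSON(sub("^#\\s*", "", hdr[1]))
    attr(template, "n_donors") <- meta$n_donors
    attr(template, "normalization") <- meta$normalization
    attr(template, "donor_auc") <- unlist(meta$donor_auc)
  }
  template
}
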