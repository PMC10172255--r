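#' Construct a table of discrete blood samples
#'
#' @param time_min Sample times, minutes post-injection (the study design
#'   draws at 2, 5, 10, 20, 30, 40 and 60 min).
#' @param whole_blood,plasma,plasma_free Gamma-counted activity, Bq/ml;
#'   `plasma_free` is the acid-soluble (non-protein-incorporated) fraction.
#' @param site `"arterial"` or `"venous"`.
#' @return A tibble of class `leu_blood`.
#' @export
blood_samples <- function(time_min, whole_blood, plasma, plasma_free,
                          site = "arterial") {
  out <- tibble::tibble(
    time_min = as.numeric(time_min),
    whole_blood = as.numeric(whole_blood),
    plasma = as.numeric(plasma),
    plasma_free = as.numeric(plasma_free),
    site = rep_len(as.character(site), length(time_min))
  )
  if (any(out$time_min < 0)) {
    stop("sample times must be non-negative.", call. = FALSE)
  }
  bad <- out$plasma_free > out$plasma + 1e-9 * pmax(1, abs(out$plasma))
  if (any(bad & out$plasma > 0)) {
    stop("plasma_free cannot exceed plasma activity.", call. = FALSE)
  }
  class(out) <- c("leu_blood", class(out))
  out
}

#' Cohort correction ratios and unlabelled leucine concentration
#'
#' @param plasma_over_wb Mean plasma/whole-blood activity ratio (0, 3].
#' @param free_fraction Mean free (acid-soluble) fraction of plasma
#'   activity, (0, 1].
#' @param leucine_conc Mean unlabelled arterial plasma leucine, nmol/ml.
#' @param provenance `"individual"` or `"population"`.
#' @return A tibble of class `leu_ratios` with one row.
#' @export
ratio_set <- function(plasma_over_wb, free_fraction, leucine_conc,
                      provenance = c("individual", "population")) {
  provenance <- match.arg(provenance)
  if (!is.finite(plasma_over_wb) || plasma_over_wb <= 0 ||
      plasma_over_wb > 3) {
    stop("plasma/whole-blood ratio must lie in (0, 3].", call. = FALSE)
  }
  if (!is.finite(free_fraction) || free_fraction <= 0 || free_fraction > 1) {
    stop("free fraction must lie in (0, 1].", call. = FALSE)
  }
  if (!is.finite(leucine_conc) || leucine_conc <= 0) {
    stop("leucine concentration must be positive.", call. = FALSE)
  }
  out <- tibble::tibble(plasma_over_wb = plasma_over_wb,
                        free_fraction = free_fraction,
                        leucine_conc = leucine_conc,
                        provenance = provenance)
  class(out) <- c("leu_ratios", class(out))
  out
}

#' Large-neutral-amino-acid plasma panel
#'
#' Concentrations (nmol/ml) of the eight LNAA sharing the LAT1 transporter
#' with leucine. Leucine is required; the others default to `NA`.
#'
#' @param leucine,isoleucine,valine,phenylalanine,tyrosine,tryptophan,histidine,methionine
#'   Concentrations in nmol/ml.
#' @param site `"arterial"` or `"venous"`.
#' @param age_months Optional age label.
#' @return A tibble of class `leu_panel` with one row.
#' @export
amino_acid_panel <- function(leucine, isoleucine = NA, valine = NA,
                             phenylalanine = NA, tyrosine = NA,
                             tryptophan = NA, histidine = NA,
                             methionine = NA, site = "arterial",
                             age_months = NA) {
  if (!is.finite(leucine) || leucine < 0) {
    stop("a non-negative leucine concentration is required.", call. = FALSE)
  }
  conc <- c(histidine = histidine, methionine = methionine,
            leucine = leucine, isoleucine = isoleucine, valine = valine,
            phenylalanine = phenylalanine, tyrosine = tyrosine,
            tryptophan = tryptophan)
  if (any(conc < 0, na.rm = TRUE)) {
    stop("amino-acid concentrations must be non-negative.", call. = FALSE)
  }
  out <- tibble::as_tibble(as.list(conc))
  out$site <- site
  out$age_months <- age_months
  class(out) <- c("leu_panel", class(out))
  out
}

#' Cohort ratios from discrete blood samples and amino-acid panels
#'
#' Computes the mean plasma/whole-blood ratio and mean free fraction over
#' usable samples, and the mean arterial unlabelled leucine over the panels.
#' Samples with non-positive whole-blood activity are excluded with a
#' warning, never silently.
#'
#' @param samples A [blood_samples()] table (rows from one or many animals).
#' @param panels A list of [amino_acid_panel()] rows, or a tibble binding
#'   them; at least one arterial panel is required.
#' @param provenance Passed to [ratio_set()].
#' @return A [ratio_set()].
#' @examples
#' s <- blood_samples(2, whole_blood = 1000, plasma = 1200, plasma_free = 960)
#' p <- amino_acid_panel(leucine = 231)
#' compute_ratios(s, list(p))
#' @export
compute_ratios <- function(samples, panels,
                           provenance = c("individual", "population")) {
  provenance <- match.arg(provenance)
  if (is.data.frame(panels)) panels <- list(panels)
  panels <- dplyr::bind_rows(panels)
  if (!nrow(panels) || !"leucine" %in% names(panels)) {
    stop("at least one amino-acid panel with leucine is required.",
         call. = FALSE)
  }
  art <- panels[panels$site %in% "arterial", , drop = FALSE]
  if (!nrow(art)) {
    stop("at least one arterial amino-acid panel is required.", call. = FALSE)
  }
  usable <- samples$whole_blood > 0 & samples$plasma > 0
  if (any(!usable)) {
    warning(sprintf("excluding %d blood sample(s) with non-positive activity.",
                    sum(!usable)), call. = FALSE)
  }
  s <- samples[usable, , drop = FALSE]
  if (!nrow(s)) stop("no usable blood samples.", call. = FALSE)
  ratio_set(
    plasma_over_wb = mean(s$plasma / s$whole_blood),
    free_fraction = mean(s$plasma_free / s$plasma),
    leucine_conc = mean(art$leucine),
    provenance = provenance
  )
}

#' Calibrate an online whole-blood detector curve against discrete samples
#'
#' The continuous shunt detector reports arbitrary units with an unknown
#' gain and a transport delay. The gain factor is the mean over usable
#' samples of (gamma-counted whole-blood activity) / (online curve value at
#' the sample time, linearly interpolated); the delay is removed by a rigid
#' shift aligning the curve's 10%-of-peak rise (located by inverse linear
#' interpolation, i.e. the threshold-crossing event an online system logs
#' at tracer appearance) to the recorded injection marker.
#'
#' @param online Online whole-blood [sampled_curve()] in detector units
#'   (decay-corrected to injection; apply [decay_correct()] first if not).
#' @param samples A [blood_samples()] table with gamma-counted whole-blood
#'   activity at times covered by the online curve.
#' @param injection_start_min Recorded injection marker, minutes (default 0).
#' @param align_delay Whether to apply the rigid time shift.
#' @return The calibrated whole-blood curve in Bq/ml, with attributes
#'   `calibration_factor` and `time_shift_min`.
#' @export
calibrate_online_curve <- function(online, samples, injection_start_min = 0,
                                   align_delay = TRUE) {
  online <- as_leu_curve(online, role = "whole_blood")
  shift <- 0
  if (align_delay) {
    peak <- max(online$value)
    if (peak <= 0) stop("online curve has no positive peak.", call. = FALSE)
    t10 <- rise_time_10pct(online$time_min, online$value)
    shift <- t10 - injection_start_min
    online <- curve_update(online, time_min = online$time_min - shift)
  }
  in_support <- samples$time_min <= max(online$time_min) + 1e-9
  s <- samples[in_support, , drop = FALSE]
  ov <- if (nrow(s)) curve_interp(online, s$time_min) else numeric(0)
  ok <- ov > 0 & s$whole_blood > 0
  if (sum(ok) < 2L) {
    stop("need >= 2 usable samples within the online curve's support ",
         "for cross-calibration.", call. = FALSE)
  }
  f <- mean(s$whole_blood[ok] / ov[ok])
  out <- curve_update(online, value = online$value * f)
  attr(out, "calibration_factor") <- f
  attr(out, "time_shift_min") <- shift
  out
}

#' Convert a whole-blood curve to a plasma free-leucine input function
#'
#' `Cp(t) = Cwb(t) * plasma_over_wb * free_fraction`, using constant cohort
#' ratios (the study design uses cohort averages; both ratios are stable over
#' the scan). Optionally, time-varying ratios interpolated linearly between
#' the discrete sample times (constant beyond them) can be used for
#' sensitivity checks.
#'
#' @param wb Calibrated, decay-corrected whole-blood [sampled_curve()].
#' @param ratios A [ratio_set()].
#' @param time_varying Optional [blood_samples()] table; when supplied, the
#'   per-sample plasma/whole-blood and free-fraction ratios are interpolated
#'   in time instead of using the cohort constants.
#' @return Plasma free-leucine input as a [sampled_curve()].
#' @export
to_plasma_free <- function(wb, ratios, time_varying = NULL) {
  wb <- as_leu_curve(wb, role = "whole_blood")
  if (is.null(time_varying)) {
    if (missing(ratios) || is.null(ratios)) {
      stop("cohort ratios are required.", call. = FALSE)
    }
    fac <- ratios$plasma_over_wb * ratios$free_fraction
    vals <- wb$value * fac
  } else {
    s <- time_varying[time_varying$whole_blood > 0 & time_varying$plasma > 0, ]
    if (nrow(s) < 2L) {
      stop("time-varying ratios need >= 2 usable samples.", call. = FALSE)
    }
    r <- (s$plasma / s$whole_blood) * (s$plasma_free / s$plasma)
    rt <- stats::approx(s$time_min, r, xout = wb$time_min, rule = 2)$y
    vals <- wb$value * rt
  }
  curve_update(wb, value = vals, role = "plasma_free")
}
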