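# Physical decay constant of carbon-11, min^-1 (half-life 20.364 min).
C11_HALF_LIFE_MIN <- 20.364
C11_LAMBDA <- log(2) / C11_HALF_LIFE_MIN

#' Construct a sampled activity curve
#'
#' A sampled curve is the package's common carrier for input functions,
#' whole-blood detector curves and tissue time-activity curves: a tibble with
#' columns `time_min` and `value`, tagged with the curve's role, units and
#' decay-correction state.
#'
#' @param time_min Sampling times in minutes, strictly increasing.
#' @param value Activity concentration at each time (Bq/ml, or dimensionless
#'   after normalization).
#' @param role One of `"plasma_free"`, `"whole_blood"`, `"tissue"`.
#' @param decay_corrected Logical; `TRUE` if values are referenced to
#'   `ref_time_min` using the carbon-11 half-life (20.364 min).
#' @param ref_time_min Reference time of the decay correction, minutes.
#' @param units Unit label carried for bookkeeping only.
#'
#' @return A tibble of class `leu_curve` with columns `time_min`, `value`.
#' @examples
#' cp <- sampled_curve(0:60, exp(-0.05 * (0:60)), role = "plasma_free")
#' curve_auc(cp)
#' @export
sampled_curve <- function(time_min, value,
                          role = c("plasma_free", "whole_blood", "tissue"),
                          decay_corrected = TRUE, ref_time_min = 0,
                          units = "Bq/ml") {
  role <- match.arg(role)
  time_min <- as.numeric(time_min)
  value <- as.numeric(value)
  if (length(time_min) != length(value)) {
    stop("`time_min` and `value` must have equal length.", call. = FALSE)
  }
  if (length(time_min) < 1L || any(!is.finite(time_min))) {
    stop("curve times must be finite and non-empty.", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("curve times must be strictly increasing.", call. = FALSE)
  }
  if (any(!is.finite(value))) {
    stop("curve values must be finite.", call. = FALSE)
  }
  out <- tibble::tibble(time_min = time_min, value = value)
  class(out) <- c("leu_curve", class(out))
  attr(out, "role") <- role
  attr(out, "decay_corrected") <- isTRUE(decay_corrected)
  attr(out, "ref_time_min") <- ref_time_min
  attr(out, "units") <- units
  out
}

curve_role <- function(curve) attr(curve, "role") %||% "tissue"

is_decay_corrected <- function(curve) isTRUE(attr(curve, "decay_corrected"))

# Rebuild a leu_curve, keeping tags unless overridden.
curve_update <- function(curve, time_min = curve$time_min, value = curve$value,
                         role = curve_role(curve),
                         decay_corrected = is_decay_corrected(curve),
                         ref_time_min = attr(curve, "ref_time_min") %||% 0,
                         units = attr(curve, "units") %||% "Bq/ml") {
  sampled_curve(time_min, value, role = role,
                decay_corrected = decay_corrected,
                ref_time_min = ref_time_min, units = units)
}

as_leu_curve <- function(x, role = "tissue", ...) {
  if (inherits(x, "leu_curve")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("time_min", "value") %in% names(x))) {
      stop("curve data frame needs columns `time_min` and `value`.",
           call. = FALSE)
    }
    return(sampled_curve(x$time_min, x$value, role = role, ...))
  }
  stop("cannot interpret object as a sampled curve.", call. = FALSE)
}

#' Linear interpolation of a sampled curve
#'
#' Values before the first sample are taken as 0 when the curve starts after
#' time zero (a tracer curve is zero before injection); extrapolation beyond
#' the last sample is an error naming the gap.
#'
#' @param curve A [sampled_curve()].
#' @param times Times (min) at which to evaluate.
#' @return Numeric vector of interpolated values.
#' @export
curve_interp <- function(curve, times) {
  curve <- as_leu_curve(curve)
  tmax <- max(curve$time_min)
  if (any(times > tmax + 1e-9)) {
    stop(sprintf(
      "evaluation time %.4g min is beyond the curve's support (ends %.4g min).",
      max(times), tmax), call. = FALSE)
  }
  t0 <- min(curve$time_min)
  tt <- curve$time_min
  vv <- curve$value
  if (t0 > 0) {
    tt <- c(0, if (t0 > 1e-12) t0 - 1e-12 else NULL, tt)
    vv <- c(0, if (t0 > 1e-12) 0 else NULL, vv)
  }
  stats::approx(tt, vv, xout = pmax(times, min(tt)), rule = 2)$y
}

#' Trapezoidal area under a sampled curve
#'
#' @param curve A [sampled_curve()] (or data frame with `time_min`, `value`).
#' @param from,to Integration window in minutes; defaults to the full support
#'   (clipped to it otherwise).
#' @return The trapezoidal integral of `value` over the window.
#' @export
curve_auc <- function(curve, from = NULL, to = NULL) {
  curve <- as_leu_curve(curve)
  from <- from %||% min(curve$time_min)
  to <- to %||% max(curve$time_min)
  if (to <= from) stop("`to` must exceed `from`.", call. = FALSE)
  knots <- sort(unique(c(curve$time_min, from, to)))
  knots <- knots[knots >= from - 1e-12 & knots <= to + 1e-12]
  v <- curve_interp(curve, knots)
  sum(diff(knots) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Apply (or remove) carbon-11 decay correction
#'
#' Rescales measured activity to a common reference time using the 20.364-min
#' carbon-11 half-life: correction multiplies values by
#' `exp(+lambda * (t - ref))`. Correcting an already-corrected curve is an
#' error; `uncorrect = TRUE` inverts the operation exactly.
#'
#' @param curve A [sampled_curve()].
#' @param ref_time_min Reference time (min) the correction refers to.
#' @param uncorrect If `TRUE`, remove an existing correction instead.
#' @return The corrected curve with its `decay_corrected` flag updated.
#' @examples
#' raw <- sampled_curve(c(0, 20.364), c(100, 50), role = "whole_blood",
#'                      decay_corrected = FALSE)
#' decay_correct(raw)$value  # 100, 100
#' @export
decay_correct <- function(curve, ref_time_min = 0, uncorrect = FALSE) {
  curve <- as_leu_curve(curve)
  if (!uncorrect && is_decay_corrected(curve)) {
    stop("curve is already decay-corrected; refusing to correct twice.",
         call. = FALSE)
  }
  if (uncorrect && !is_decay_corrected(curve)) {
    stop("curve is not decay-corrected; nothing to undo.", call. = FALSE)
  }
  sign <- if (uncorrect) -1 else +1
  fac <- exp(sign * C11_LAMBDA * (curve$time_min - ref_time_min))
  curve_update(curve, value = curve$value * fac,
               decay_corrected = !uncorrect, ref_time_min = ref_time_min)
}

#' Construct a PET frame schedule
#'
#' @param start_min,end_min Frame start and end times in minutes; frames must
#'   be non-overlapping and strictly increasing with positive durations.
#' @return A tibble of class `leu_schedule` with columns `frame`,
#'   `start_min`, `end_min`, `mid_min`, `dur_min`.
#' @export
frame_schedule <- function(start_min, end_min) {
  start_min <- as.numeric(start_min)
  end_min <- as.numeric(end_min)
  if (length(start_min) != length(end_min) || length(start_min) < 1L) {
    stop("`start_min` and `end_min` must be equal-length, non-empty.",
         call. = FALSE)
  }
  if (any(end_min <= start_min)) {
    stop("every frame must have positive duration.", call. = FALSE)
  }
  if (any(diff(start_min) <= 0) ||
      any(utils::head(end_min, -1) > utils::tail(start_min, -1) + 1e-9)) {
    stop("frames must be non-overlapping and strictly increasing.",
         call. = FALSE)
  }
  out <- tibble::tibble(
    frame = seq_along(start_min),
    start_min = start_min,
    end_min = end_min,
    mid_min = (start_min + end_min) / 2,
    dur_min = end_min - start_min
  )
  class(out) <- c("leu_schedule", class(out))
  out
}

#' Default 60-minute rat acquisition frame schedule
#'
#' 12 x 10 s, 6 x 30 s, 5 x 60 s, 10 x 300 s = 33 frames over 60 min.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(10 / 60, 12), rep(30 / 60, 6), rep(1, 5), rep(5, 10))
  ends <- cumsum(dur)
  frame_schedule(ends - dur, ends)
}

#' Frame-average a finely sampled curve
#'
#' Time-averages a sampled curve over each frame of a schedule (trapezoidal
#' rule on the curve's grid plus the frame edges). Intended for curves
#' sampled at least ~10x finer than the shortest frame; the model-side fit
#' uses exact analytic frame means instead (see [solve_model_frames()]).
#'
#' @param ct A [sampled_curve()].
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of per-frame mean values.
#' @export
frame_average <- function(ct, schedule) {
  ct <- as_leu_curve(ct)
  if (max(schedule$end_min) > max(ct$time_min) + 1e-9 ||
      min(schedule$start_min) < min(c(0, ct$time_min)) - 1e-9) {
    stop("schedule extends beyond the sampled curve's support.", call. = FALSE)
  }
  vapply(seq_len(nrow(schedule)), function(i) {
    curve_auc(ct, schedule$start_min[i], schedule$end_min[i]) /
      schedule$dur_min[i]
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
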