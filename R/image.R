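# Dynamic images are 4D arrays (x, y, z, frame) of activity in Bq/ml
# (1 cm^3 is taken as 1 ml throughout); masks are 3D logical/0-1 arrays on
# the same voxel grid. Either may be given as a NIfTI file path.

load_image_4d <- function(image) {
  if (is.character(image)) image <- RNifti::readNifti(image)
  img <- unclass(image)
  if (length(dim(img)) != 4L) {
    stop("a 4D dynamic image (x, y, z, frame) is required.", call. = FALSE)
  }
  img
}

load_mask_3d <- function(mask, image_dim) {
  if (is.character(mask)) mask <- RNifti::readNifti(mask)
  m <- unclass(mask)
  if (length(dim(m)) != 3L) {
    stop("mask must be a 3D volume.", call. = FALSE)
  }
  if (!all(dim(m) == image_dim[1:3])) {
    stop(sprintf("mask grid %s does not match image grid %s.",
                 paste(dim(m), collapse = "x"),
                 paste(image_dim[1:3], collapse = "x")), call. = FALSE)
  }
  m <- m != 0
  if (!any(m)) stop("mask is empty.", call. = FALSE)
  m
}

roi_frame_means <- function(img, m) {
  nframe <- dim(img)[4]
  vox <- which(m)
  nvox <- prod(dim(img)[1:3])
  vapply(seq_len(nframe), function(f) {
    mean(img[vox + (f - 1L) * nvox])
  }, numeric(1))
}

#' Region-of-interest time-activity curve from a dynamic image
#'
#' Per-frame mean of the voxels inside a mask, timestamped at the frame
#' mid-times.
#'
#' @param image 4D array (x, y, z, frame) in Bq/ml, or a NIfTI path.
#' @param mask 3D array (non-zero = inside) on the same grid, or a NIfTI
#'   path.
#' @param schedule A [frame_schedule()] with one frame per image volume.
#' @return A tissue [sampled_curve()] at the frame mid-times.
#' @export
roi_tac <- function(image, mask, schedule) {
  img <- load_image_4d(image)
  if (dim(img)[4] != nrow(schedule)) {
    stop("image has a different number of frames than the schedule.",
         call. = FALSE)
  }
  m <- load_mask_3d(mask, dim(img))
  sampled_curve(schedule$mid_min, roi_frame_means(img, m), role = "tissue")
}

#' Image-derived input function from a left-ventricle mask
#'
#' Identical extraction to [roi_tac()] but tagged as a whole-blood curve:
#' the left-ventricle blood pool tracks arterial whole-blood activity and is
#' used to scale the population-based input function (see [scale_pbif()]).
#'
#' @inheritParams roi_tac
#' @param lv_mask Left-ventricle mask, 3D array or NIfTI path.
#' @return A whole-blood [sampled_curve()] at the frame mid-times.
#' @export
extract_idif <- function(image, lv_mask, schedule) {
  img <- load_image_4d(image)
  if (dim(img)[4] != nrow(schedule)) {
    stop("image has a different number of frames than the schedule.",
         call. = FALSE)
  }
  m <- load_mask_3d(lv_mask, dim(img))
  sampled_curve(schedule$mid_min, roi_frame_means(img, m),
                role = "whole_blood")
}

#' Subject metadata for SUV normalization
#'
#' @param body_weight_g Body weight, grams (> 0).
#' @param injected_dose_MBq Injected activity, MBq (> 0).
#' @param injection_time_min Injection time relative to scan start, min.
#' @param genotype,age_months Optional study labels.
#' @return A tibble of class `leu_meta` with one row.
#' @export
subject_meta <- function(body_weight_g, injected_dose_MBq,
                         injection_time_min = 0, genotype = NA_character_,
                         age_months = NA_real_) {
  if (!is.finite(body_weight_g) || body_weight_g <= 0) {
    stop("body weight must be positive.", call. = FALSE)
  }
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0) {
    stop("injected dose must be positive.", call. = FALSE)
  }
  out <- tibble::tibble(body_weight_g = body_weight_g,
                        injected_dose_MBq = injected_dose_MBq,
                        injection_time_min = injection_time_min,
                        genotype = genotype, age_months = age_months)
  class(out) <- c("leu_meta", class(out))
  out
}

#' Standardized uptake value
#'
#' `SUV = activity (Bq/cm^3) x 1e-6 x body weight (g) / injected dose (MBq)`,
#' dimensionless under the 1 cm^3 = 1 ml = 1 g tissue convention.
#' Vectorizes over voxels or frames.
#'
#' @param activity Activity concentration, Bq/cm^3 (vector, matrix or
#'   array).
#' @param meta A [subject_meta()].
#' @return SUV, same shape as `activity`.
#' @examples
#' suv(1e6, subject_meta(300, 37.7))  # 7.9576
#' @export
suv <- function(activity, meta) {
  activity * 1e-6 * meta$body_weight_g / meta$injected_dose_MBq
}

#' Duration-weighted summed image over a time window
#'
#' Sums `frame x duration` over frames whose mid-time falls in the window
#' (mid-time assignment keeps the rule schedule-robust). The default 20-60
#' min window shows late, predominantly trapped uptake.
#'
#' @inheritParams roi_tac
#' @param window Numeric `c(t0, t1)` in minutes.
#' @return A 3D array: integral of activity over the window (Bq·min/ml).
#' @export
summed_image <- function(image, schedule, window = c(20, 60)) {
  img <- load_image_4d(image)
  use <- which(schedule$mid_min >= window[1] - 1e-9 &
                 schedule$mid_min <= window[2] + 1e-9)
  if (!length(use)) {
    stop("no frames have mid-times inside the summing window.",
         call. = FALSE)
  }
  out <- array(0, dim = dim(img)[1:3])
  for (f in use) {
    out <- out + array(img[, , , f], dim(img)[1:3]) * schedule$dur_min[f]
  }
  out
}

#' Mean activity of a TAC over a time window
#'
#' Duration-weighted mean of the frames with mid-times inside the window;
#' the regional SUV reported in study tables is [suv()] of this value.
#'
#' @param tac Per-frame tissue values (numeric) or a tissue curve at frame
#'   mid-times.
#' @param schedule A [frame_schedule()].
#' @param window Numeric `c(t0, t1)` in minutes.
#' @return Mean activity over the window.
#' @export
window_mean <- function(tac, schedule, window = c(20, 60)) {
  if (is.data.frame(tac)) tac <- tac$value
  use <- schedule$mid_min >= window[1] - 1e-9 &
    schedule$mid_min <= window[2] + 1e-9
  if (!any(use)) stop("no frames inside the window.", call. = FALSE)
  sum(tac[use] * schedule$dur_min[use]) / sum(schedule$dur_min[use])
}
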