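#' Tri-exponential bolus input-function model
#'
#' `Cp(t) = (A1*(t - tau) - A2 - A3) * exp(-l1*(t - tau)) +
#' A2*exp(-l2*(t - tau)) + A3*exp(-l3*(t - tau))` for `t >= tau`, zero
#' before: the standard bolus-injection form with a sharp first-pass peak
#' and a slowly clearing tail, emulating a 30-s tail-vein bolus.
#'
#' @param params Named list: amplitudes `A1` (Bq/ml/min), `A2`, `A3`
#'   (Bq/ml), rates `l1 > l2 > l3 > 0` (min^-1), appearance time `tau`
#'   (min).
#' @param times Evaluation times, min.
#' @return A plasma-free [sampled_curve()] on `times`.
#' @examples
#' cp <- make_aif(default_aif_params(), pbif_grid())
#' @export
make_aif <- function(params, times) {
  p <- params
  need <- c("A1", "A2", "A3", "l1", "l2", "l3", "tau")
  if (!all(need %in% names(p))) {
    stop("aif parameters must include ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!(p$l1 > p$l2 && p$l2 > p$l3 && p$l3 > 0)) {
    stop("decay rates must satisfy l1 > l2 > l3 > 0.", call. = FALSE)
  }
  times <- as.numeric(times)
  u <- times - p$tau
  v <- ifelse(u < 0, 0,
              (p$A1 * u - p$A2 - p$A3) * exp(-p$l1 * u) +
                p$A2 * exp(-p$l2 * u) + p$A3 * exp(-p$l3 * u))
  neg <- v < -1e-9 * max(abs(v), 1)
  if (any(neg)) {
    stop(sprintf("aif parameters produce a negative value at t = %.4g min.",
                 times[which(neg)[1]]), call. = FALSE)
  }
  sampled_curve(times, pmax(v, 0), role = "plasma_free")
}

#' Default bolus parameters for a rat [11C]leucine study
#'
#' Peak ~120 kBq/ml about 0.4 min after appearance, with a slow tail of a
#' few kBq/ml at 60 min — the scale expected for a ~37.7 MBq bolus in a
#' ~400-g rat.
#'
#' @return Named list of [make_aif()] parameters.
#' @export
default_aif_params <- function() {
  list(A1 = 8e5, A2 = 2e4, A3 = 1.2e4, l1 = 2.5, l2 = 0.35, l3 = 0.015,
       tau = 0.25)
}

#' Default true rate constants per brain region
#'
#' Three regions spanning the parameter ranges the fit is validated over
#' (fast/slow efflux, high/low trapping) at physiological transport rates;
#' at the cohort-mean leucine of 228 nmol/ml the implied PSR values are
#' 5.7, 5.7 and 4.6 nmol/ml/min (`PSR = K1*k3*leu/k2`).
#'
#' @return Tibble with columns `region`, `K1`, `k2`, `k3`.
#' @export
default_regions <- function() {
  tibble::tribble(
    ~region, ~K1, ~k2, ~k3,
    "frontoparietal_cortex", 0.10, 0.20, 0.05,
    "hippocampus", 0.05, 0.10, 0.05,
    "thalamus", 0.05, 0.05, 0.02
  )
}

#' Specification of a synthetic [11C]leucine study
#'
#' Bundles every generator setting: the frame schedule, true regional rate
#' constants, bolus shape, blood-sampling design, correction ratios,
#' leucine distribution and the noise model. All randomness derives from
#' `seed` via a per-subject splitting scheme (see [generate_subject()]), so
#' a spec reproduces a study bit-identically.
#'
#' @param seed Master seed (integer).
#' @param schedule A [frame_schedule()].
#' @param regions Tibble of true `region`, `K1`, `k2`, `k3`.
#' @param aif_params [make_aif()] parameters of the cohort-mean bolus.
#' @param aif_amp_jitter Half-width of the uniform per-subject amplitude
#'   factor (0.15 = +/-15%).
#' @param aif_shape_jitter_sd Log-normal SD applied to `l2`, `l3` per
#'   subject (mild physiological shape variation).
#' @param sample_times_min Discrete blood-sample times, min.
#' @param plasma_over_wb,free_fraction Cohort-true correction ratios.
#' @param ratio_jitter_sd Log-normal SD of per-subject ratio variation.
#' @param leucine_mean,leucine_sd Arterial unlabelled leucine, nmol/ml.
#' @param venous_offset Fractional venous-minus-arterial leucine offset
#'   (default -0.27).
#' @param noise_sigma TAC noise scale: per-frame SD =
#'   `noise_sigma * sqrt(CT / frame duration)` (counting-statistics shape);
#'   0 disables TAC noise.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (resampling on
#'   the implied counts scale).
#' @param online_noise_cv Multiplicative CV of the online detector.
#' @param sample_noise_cv Multiplicative CV of gamma-counted samples and
#'   amino-acid assays.
#' @param online_delay_min Transport delay of the online detector, min.
#' @param online_gain_range Range of the arbitrary detector gain.
#' @param anisomycin_k3_mult k3 multiplier in the anisomycin arm (0.14
#'   gives ~86% PSR inhibition, inside the observed 77-89% range).
#' @param bw_mean_g,bw_sd_g Body weight distribution, g.
#' @param dose_mean_MBq,dose_sd_MBq Injected dose distribution, MBq.
#' @return A list of class `leu_cohort_spec`.
#' @export
cohort_spec <- function(seed = 1L,
                        schedule = default_frame_schedule(),
                        regions = default_regions(),
                        aif_params = default_aif_params(),
                        aif_amp_jitter = 0.15,
                        aif_shape_jitter_sd = 0.03,
                        sample_times_min = c(2, 5, 10, 20, 30, 40, 60),
                        plasma_over_wb = 1.2,
                        free_fraction = 0.8,
                        ratio_jitter_sd = 0.02,
                        leucine_mean = 228,
                        leucine_sd = 15,
                        venous_offset = -0.27,
                        noise_sigma = 10,
                        noise_model = c("gaussian", "poisson"),
                        online_noise_cv = 0.02,
                        sample_noise_cv = 0.01,
                        online_delay_min = 0.1,
                        online_gain_range = c(0.3, 3),
                        anisomycin_k3_mult = 0.14,
                        bw_mean_g = 450, bw_sd_g = 40,
                        dose_mean_MBq = 37.7, dose_sd_MBq = 7.45) {
  noise_model <- match.arg(noise_model)
  stopifnot(nrow(regions) >= 1, all(c("region", "K1", "k2", "k3") %in%
                                      names(regions)))
  for (i in seq_len(nrow(regions))) {
    rate_constants(regions$K1[i], regions$k2[i], regions$k3[i])  # validate
  }
  if (anisomycin_k3_mult <= 0) {
    stop("anisomycin k3 multiplier must be positive.", call. = FALSE)
  }
  spec <- list(
    seed = as.integer(seed), schedule = schedule, regions = regions,
    aif_params = aif_params, aif_amp_jitter = aif_amp_jitter,
    aif_shape_jitter_sd = aif_shape_jitter_sd,
    sample_times_min = sample_times_min,
    plasma_over_wb = plasma_over_wb, free_fraction = free_fraction,
    ratio_jitter_sd = ratio_jitter_sd,
    leucine_mean = leucine_mean, leucine_sd = leucine_sd,
    venous_offset = venous_offset,
    noise_sigma = noise_sigma, noise_model = noise_model,
    online_noise_cv = online_noise_cv, sample_noise_cv = sample_noise_cv,
    online_delay_min = online_delay_min,
    online_gain_range = online_gain_range,
    anisomycin_k3_mult = anisomycin_k3_mult,
    bw_mean_g = bw_mean_g, bw_sd_g = bw_sd_g,
    dose_mean_MBq = dose_mean_MBq, dose_sd_MBq = dose_sd_MBq
  )
  class(spec) <- "leu_cohort_spec"
  spec
}

#' A fully noise-free variant of a cohort spec
#'
#' Zeroes every noise source and per-subject jitter (amplitude jitter on
#' the bolus is kept: it is subject truth, not noise) so that pipeline
#' round trips are exact up to optimizer tolerance.
#'
#' @param spec A [cohort_spec()].
#' @return The spec with all noise and ratio/shape jitter set to zero.
#' @export
noise_free <- function(spec) {
  spec$noise_sigma <- 0
  spec$online_noise_cv <- 0
  spec$sample_noise_cv <- 0
  spec$ratio_jitter_sd <- 0
  spec$aif_shape_jitter_sd <- 0
  spec$online_delay_min <- 0
  spec
}

#' k3 multiplier that sets a region's true mean PSR
#'
#' Because `PSR = Kcplx*leu/lambda = K1*k3*leu/k2`, PSR is linear in k3:
#' scaling k3 by `m` scales PSR by `m` exactly. Returns the multiplier that
#' makes the cohort-mean true PSR of `region` equal `target_psr`.
#'
#' @param spec A [cohort_spec()].
#' @param region Region name in `spec$regions`.
#' @param target_psr Desired cohort-mean PSR, nmol/ml/min.
#' @return The k3 multiplier.
#' @export
k3_multiplier_for_psr <- function(spec, region, target_psr) {
  r <- spec$regions[spec$regions$region == region, ]
  if (!nrow(r)) stop("unknown region: ", region, call. = FALSE)
  base <- r$K1 * r$k3 * spec$leucine_mean / r$k2
  target_psr / base
}

# Deterministic per-subject substream: a distinct, reproducible seed for
# each (master seed, arm, subject index) triple, kept inside 32-bit range.
subject_seed <- function(seed, index, arm) {
  arm_off <- if (identical(arm, "anisomycin")) 500009L else 0L
  as.integer((as.double(seed) * 10007 + index * 7919 + arm_off) %%
               2147483647)
}

rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -0.5 * log(1 + cv^2),
                sdlog = sqrt(log(1 + cv^2)))
}

# 10%-of-peak crossing time by inverse linear interpolation (the event
# marker an online detector logs at tracer appearance).
rise_time_10pct <- function(time_min, value) {
  peak <- max(value)
  thr <- 0.1 * peak
  i <- which(value >= thr)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(time_min[1])
  t0 <- time_min[i - 1L]; t1 <- time_min[i]
  v0 <- value[i - 1L]; v1 <- value[i]
  t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
}

# Grid the online detector samples on: 3-s sampling, run past the end of
# the acquisition so delay alignment never truncates the 0-60 min support.
online_grid <- function() seq(0, 61, by = 0.05)

#' Generate one synthetic subject
#'
#' Draws subject truth (bolus, rate constants, ratios, leucine, body
#' weight, dose), then produces everything the pipeline consumes: the true
#' plasma-free input function, a gain- and delay-corrupted online
#' whole-blood detector curve (not decay-corrected, as acquired), seven
#' discrete gamma-counted blood samples at the design times, arterial and
#' venous amino-acid panels, noisy regional frame TACs, and subject
#' metadata. TAC noise is additive Gaussian with per-frame SD
#' `sigma*sqrt(CT/dt)` (or Poisson resampling on the implied counts scale).
#'
#' @param spec A [cohort_spec()].
#' @param index Subject index within the arm (1-based).
#' @param arm `"baseline"` or `"anisomycin"` (k3 scaled by
#'   `spec$anisomycin_k3_mult`).
#' @return A list of class `leu_subject` with elements `subject`, `arm`,
#'   `truth` (true parameters, per-region true PSR, ratios, leucine),
#'   `aif`, `wb` (true whole-blood curve), `online`, `injection_marker_min`,
#'   `samples`, `panels`, `tacs` (tibble: region x frame activity),
#'   `schedule`, `meta`.
#' @export
generate_subject <- function(spec, index, arm = c("baseline", "anisomycin")) {
  arm <- match.arg(arm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed(spec$seed, index, arm))

  # --- subject truth ---------------------------------------------------
  p <- spec$aif_params
  amp <- stats::runif(1, 1 - spec$aif_amp_jitter, 1 + spec$aif_amp_jitter)
  shape <- exp(stats::rnorm(2, 0, spec$aif_shape_jitter_sd))
  p$A1 <- p$A1 * amp; p$A2 <- p$A2 * amp; p$A3 <- p$A3 * amp
  p$l2 <- min(p$l2 * shape[1], 0.99 * p$l1)
  p$l3 <- min(p$l3 * shape[2], 0.99 * p$l2)
  por <- min(spec$plasma_over_wb * rlnorm_cv(1, spec$ratio_jitter_sd), 3)
  ff <- min(spec$free_fraction * rlnorm_cv(1, spec$ratio_jitter_sd), 1)
  leu <- max(stats::rnorm(1, spec$leucine_mean, spec$leucine_sd), 1)
  k3_mult <- if (arm == "anisomycin") spec$anisomycin_k3_mult else 1
  regions <- spec$regions
  regions$k3 <- regions$k3 * k3_mult
  regions$lambda <- regions$k2 / (regions$k2 + regions$k3)
  regions$Kcplx <- regions$K1 * regions$k3 / (regions$k2 + regions$k3)
  regions$PSR <- regions$Kcplx * leu / regions$lambda

  # --- curves ----------------------------------------------------------
  aif <- make_aif(p, pbif_grid())
  wb_fac <- 1 / (por * ff)
  wb <- curve_update(aif, value = aif$value * wb_fac, role = "whole_blood")

  og <- online_grid()
  delay <- spec$online_delay_min
  gain <- stats::runif(1, spec$online_gain_range[1],
                       spec$online_gain_range[2])
  wb_at <- function(t) {
    tt <- pmin(pmax(t, 0), max(wb$time_min))
    ifelse(t > max(wb$time_min), wb$value[length(wb$value)],
           curve_interp(wb, tt))
  }
  clean_online <- wb_at(og - delay) * exp(-C11_LAMBDA * pmax(og - delay, 0))
  # the event marker the console logs: 10%-of-peak crossing of the
  # (decay-corrected) undelayed blood curve
  marker <- rise_time_10pct(og, wb_at(og))
  online_vals <- clean_online * gain *
    rlnorm_cv(length(og), spec$online_noise_cv)
  online <- sampled_curve(og, online_vals, role = "whole_blood",
                          decay_corrected = FALSE, units = "detector")

  # --- discrete blood samples and panels -------------------------------
  st <- spec$sample_times_min
  wb_s <- wb_at(st)
  samples <- blood_samples(
    st,
    whole_blood = wb_s * rlnorm_cv(length(st), spec$sample_noise_cv),
    plasma = wb_s * por * rlnorm_cv(length(st), spec$sample_noise_cv),
    plasma_free = wb_s * por * ff * rlnorm_cv(length(st),
                                              spec$sample_noise_cv),
    site = "arterial"
  )
  lnaa <- c(isoleucine = 95, valine = 185, phenylalanine = 65,
            tyrosine = 70, tryptophan = 80, histidine = 60,
            methionine = 45)
  panel_noise <- rlnorm_cv(1 + length(lnaa), spec$sample_noise_cv)
  art_panel <- amino_acid_panel(
    leucine = leu * panel_noise[1],
    isoleucine = lnaa["isoleucine"] * panel_noise[2],
    valine = lnaa["valine"] * panel_noise[3],
    phenylalanine = lnaa["phenylalanine"] * panel_noise[4],
    tyrosine = lnaa["tyrosine"] * panel_noise[5],
    tryptophan = lnaa["tryptophan"] * panel_noise[6],
    histidine = lnaa["histidine"] * panel_noise[7],
    methionine = lnaa["methionine"] * panel_noise[8],
    site = "arterial"
  )
  ven_panel <- art_panel
  ven_panel$leucine <- art_panel$leucine * (1 + spec$venous_offset)
  ven_panel$site <- "venous"

  # --- regional TACs ---------------------------------------------------
  sch <- spec$schedule
  tacs <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    rc <- rate_constants(regions$K1[i], regions$k2[i], regions$k3[i])
    mu <- solve_model_frames(rc, aif, sch)
    act <- if (spec$noise_sigma <= 0) {
      mu
    } else if (spec$noise_model == "gaussian") {
      mu + stats::rnorm(length(mu)) * spec$noise_sigma *
        sqrt(pmax(mu, 0) / sch$dur_min)
    } else {
      scale_ <- sch$dur_min / spec$noise_sigma^2
      stats::rpois(length(mu), pmax(mu, 0) * scale_) / scale_
    }
    tibble::tibble(region = regions$region[i], frame = sch$frame,
                   frame_start_min = sch$start_min,
                   frame_end_min = sch$end_min,
                   activity_Bq_per_ml = act, true_mean = mu)
  })

  meta <- subject_meta(
    body_weight_g = max(stats::rnorm(1, spec$bw_mean_g, spec$bw_sd_g), 100),
    injected_dose_MBq = max(stats::rnorm(1, spec$dose_mean_MBq,
                                         spec$dose_sd_MBq), 5)
  )

  structure(list(
    subject = sprintf("%s%02d", substr(arm, 1, 1), index),
    arm = arm,
    truth = list(regions = regions, plasma_over_wb = por,
                 free_fraction = ff, leucine = leu, aif_params = p,
                 gain = gain, delay_min = delay),
    aif = aif, wb = wb, online = online,
    injection_marker_min = marker,
    samples = samples,
    panels = list(arterial = art_panel, venous = ven_panel),
    tacs = tacs, schedule = sch, meta = meta
  ), class = "leu_subject")
}

#' Generate an arm of synthetic subjects
#'
#' @param spec A [cohort_spec()].
#' @param n Number of subjects.
#' @param arm `"baseline"` or `"anisomycin"`.
#' @return List of [generate_subject()] bundles.
#' @export
generate_cohort <- function(spec, n, arm = "baseline") {
  purrr::map(seq_len(n), function(i) generate_subject(spec, i, arm))
}

# Save/restore the global RNG state so generators are pure functions of
# (spec, index) and never perturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Miniature dynamic phantom from a synthetic subject
#'
#' A small 4D volume in which left-ventricle voxels carry the subject's
#' whole-blood frame means, each brain-region block carries that region's
#' TAC, and the background is zero; optional additive Gaussian voxel noise.
#' Grids above 32 voxels per axis are refused (this is a desk-scale test
#' object, not a scanner simulation).
#'
#' @param bundle A [generate_subject()] bundle.
#' @param dim 3-vector of voxel grid dimensions (each <= 32).
#' @param noise_sd Additive Gaussian SD per voxel per frame (Bq/ml).
#' @param seed Seed for the voxel noise.
#' @return List of class `leu_phantom`: `image` (4D array), `masks` (named
#'   list of 3D arrays: `left_ventricle` plus one per region), `schedule`,
#'   `frame_sidecar` (tibble).
#' @export
generate_phantom <- function(bundle, dim = c(16, 16, 8), noise_sd = 0,
                             seed = 1L) {
  if (length(dim) != 3L || any(dim > 32) || any(dim < 4)) {
    stop("phantom grid must be 3D with 4..32 voxels per axis.",
         call. = FALSE)
  }
  sch <- bundle$schedule
  nf <- nrow(sch)
  img <- array(0, c(dim, nf))
  regions <- unique(bundle$tacs$region)
  n_blocks <- length(regions) + 1L
  # contiguous equal x-slabs: block 1 = LV, then one per region
  cuts <- floor(seq(0, dim[1], length.out = n_blocks + 1L))
  masks <- list()
  zmid <- seq(max(1, dim[3] %/% 4), max(2, 3 * dim[3] %/% 4))
  ymid <- seq(max(1, dim[2] %/% 4), max(2, 3 * dim[2] %/% 4))
  lv_curve <- frame_average(bundle$wb, sch)
  for (b in seq_len(n_blocks)) {
    m <- array(FALSE, dim)
    xs <- seq(cuts[b] + 1L, cuts[b + 1L])
    m[xs, ymid, zmid] <- TRUE
    vals <- if (b == 1L) {
      lv_curve
    } else {
      bundle$tacs$activity_Bq_per_ml[bundle$tacs$region == regions[b - 1L]]
    }
    for (f in seq_len(nf)) {
      vol <- img[, , , f]
      vol[m] <- vals[f]
      img[, , , f] <- vol
    }
    masks[[if (b == 1L) "left_ventricle" else regions[b - 1L]]] <- m
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), c(dim, nf))
  }
  structure(list(
    image = img, masks = masks, schedule = sch,
    frame_sidecar = tibble::tibble(frame = sch$frame,
                                   frame_start_min = sch$start_min,
                                   frame_end_min = sch$end_min)
  ), class = "leu_phantom")
}

#' Write a phantom to NIfTI files with a frame-time sidecar
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image = file.path(dir, "dynamic.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$image), paths[["image"]])
  for (nm in names(phantom$masks)) {
    p <- file.path(dir, paste0("mask_", nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(phantom$masks[[nm]] * 1L), p)
    paths[nm] <- p
  }
  sidecar <- file.path(dir, "frames.tsv")
  readr::write_tsv(phantom$frame_sidecar, sidecar)
  paths["frames"] <- sidecar
  invisible(paths)
}
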