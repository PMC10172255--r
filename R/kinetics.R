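#' Rate constants of the irreversible leucine model
#'
#' The model has two tissue compartments: free (precursor) leucine `Cf` fed
#' from plasma at `K1` and cleared back at `k2`, and a protein-bound pool
#' `Cb` filled irreversibly at `k3`. Recycling of label out of protein
#' (`krec`) is taken as zero on the 60-min time scale of a carbon-11 scan.
#'
#' @param K1 Plasma-to-tissue transfer, ml·ml^-1·min^-1; must be > 0.
#' @param k2 Tissue-to-plasma efflux, min^-1; >= 0.
#' @param k3 Incorporation into protein, min^-1; >= 0. `k2 + k3` must be > 0.
#' @param krec Protein-to-precursor recycling, min^-1; fixed at 0.
#' @return A tibble of class `leu_rc` with one row.
#' @examples
#' rc <- rate_constants(K1 = 0.05, k2 = 0.1, k3 = 0.05)
#' compute_lambda(rc)
#' compute_kcplx(rc)
#' @export
rate_constants <- function(K1, k2, k3, krec = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, krec = krec)
  if (any(!is.finite(vals))) {
    stop("rate constants must be finite.", call. = FALSE)
  }
  if (K1 <= 0) stop("K1 must be positive.", call. = FALSE)
  if (k2 < 0 || k3 < 0) stop("k2 and k3 must be non-negative.", call. = FALSE)
  if (k2 + k3 <= 0) stop("k2 + k3 must be positive.", call. = FALSE)
  if (krec != 0) {
    stop("krec is fixed at 0 in this model (no recycling within 60 min).",
         call. = FALSE)
  }
  out <- tibble::tibble(K1 = K1, k2 = k2, k3 = k3, krec = krec)
  class(out) <- c("leu_rc", class(out))
  out
}

as_rc <- function(rc) {
  if (inherits(rc, "leu_rc")) return(rc)
  if (is.numeric(rc) && !is.null(names(rc))) {
    return(rate_constants(rc[["K1"]], rc[["k2"]], rc[["k3"]]))
  }
  if (is.list(rc) && all(c("K1", "k2", "k3") %in% names(rc))) {
    return(rate_constants(rc$K1, rc$k2, rc$k3))
  }
  stop("cannot interpret object as rate constants.", call. = FALSE)
}

#' Precursor-pool dilution factor lambda
#'
#' `lambda = k2 / (k2 + k3)`: the fraction of the tissue precursor pool that
#' derives from plasma rather than from proteolysis, used to correct PSR for
#' recycled unlabelled leucine.
#'
#' @param rc A [rate_constants()] object (or named list with `k2`, `k3`).
#' @return Dimensionless scalar in (0, 1].
#' @export
compute_lambda <- function(rc) {
  rc <- as_rc(rc)
  rc$k2 / (rc$k2 + rc$k3)
}

#' Unidirectional uptake (trapping) rate Kcplx
#'
#' `Kcplx = K1 * k3 / (k2 + k3)`: the net influx rate of plasma leucine into
#' the irreversible protein pool, min^-1.
#'
#' @inheritParams compute_lambda
#' @return Kcplx in min^-1.
#' @export
compute_kcplx <- function(rc) {
  rc <- as_rc(rc)
  rc$K1 * rc$k3 / (rc$k2 + rc$k3)
}

#' Protein synthesis rate
#'
#' `PSR = Kcplx * leu / lambda`, in nmol of leucine incorporated per ml of
#' tissue per minute; `leu` is the unlabelled leucine concentration in
#' arterial plasma (nmol/ml), and the division by `lambda` corrects for
#' precursor-pool dilution by proteolysis-derived leucine.
#'
#' @param kcplx Trapping rate, min^-1 (>= 0).
#' @param lambda_ Precursor dilution factor in (0, 1].
#' @param leu Unlabelled arterial plasma leucine, nmol/ml (> 0).
#' @return PSR in nmol·ml^-1·min^-1.
#' @examples
#' compute_psr(0.0166667, 0.666667, 231)
#' @export
compute_psr <- function(kcplx, lambda_, leu) {
  if (any(kcplx < 0)) stop("Kcplx must be non-negative.", call. = FALSE)
  if (any(lambda_ <= 0) || any(lambda_ > 1)) {
    stop("lambda must lie in (0, 1].", call. = FALSE)
  }
  if (any(leu <= 0)) {
    stop("unlabelled leucine concentration must be positive.", call. = FALSE)
  }
  kcplx * leu / lambda_
}

# Exact convolution tables for a piecewise-linear input.
#
# Given input knots (tt, pp) with tt[1] == 0 and decay rate a = k2 + k3,
# returns at every knot:
#   I = integral of Cp,            E = int_0^t exp(-a(t-s)) Cp(s) ds,
#   J = integral of I,             F = integral of E.
# All four are exact for the piecewise-linear input (the E recurrence
# integrates each linear segment in closed form; F uses the segment-wise
# identity  int E = (int Cp - delta E) / a  from E' = Cp - aE).
conv_tables <- function(tt, pp, a, want_JF = FALSE) {
  n <- length(tt)
  dt <- diff(tt)
  p0 <- pp[-n]
  p1 <- pp[-1L]
  m <- (p1 - p0) / dt
  b <- a * dt
  eb <- exp(-b)
  phi1 <- -expm1(-b) / a
  psi <- ifelse(
    b > 1e-4,
    (1 - (1 + b) * eb) / a^2,
    dt^2 * (0.5 - b / 3 + b^2 / 8 - b^3 / 30)
  )
  phi2 <- dt * phi1 - psi
  seg_conv <- p0 * phi1 + m * phi2
  seg_trap <- dt * (p0 + p1) / 2

  # First-order recurrence E[i+1] = E[i]*exp(-b[i]) + seg_conv[i],
  # vectorized as a rescaled cumulative sum. Blocks bound the exponent of
  # the rescaling so exp() never overflows even for fast kinetics.
  E <- numeric(n)
  block <- cumsum(c(0, b)) %/% 500
  i <- 1L
  while (i < n) {
    last <- max(which(block == block[i]))
    if (last == i) {                        # single wide segment: scalar step
      E[i + 1L] <- E[i] * eb[i] + seg_conv[i]
      i <- i + 1L
      next
    }
    j <- i:(last - 1L)                      # segment indices in this block
    s <- cumsum(b[j])                       # a*(t[j+1] - t[i])
    cs <- cumsum(seg_conv[j] * exp(s))
    E[j + 1L] <- exp(-s) * (E[i] + cs)
    i <- last
  }
  I <- c(0, cumsum(seg_trap))
  out <- list(t = tt, I = I, E = E)
  if (want_JF) {
    segJ <- I[-n] * dt + p0 * dt^2 / 2 + m * dt^3 / 6
    segF <- (seg_trap - diff(E)) / a
    out$J <- c(0, cumsum(segJ))
    out$F <- c(0, cumsum(segF))
  }
  out
}

# Knot grid for the convolution: input-curve knots unified with extra times,
# zero-padded back to t = 0. Input values at the knots come from linear
# interpolation, so the piecewise-linear input is represented exactly.
conv_knots <- function(cp, extra_times) {
  cp <- as_leu_curve(cp)
  tmax <- max(extra_times)
  if (max(cp$time_min) < tmax - 1e-9) {
    stop(sprintf(
      "input function ends at %.4g min but evaluation requires %.4g min.",
      max(cp$time_min), tmax), call. = FALSE)
  }
  tt <- sort(unique(c(0, cp$time_min[cp$time_min <= tmax + 1e-12],
                      extra_times)))
  tt <- tt[tt >= 0]
  # collapse knots closer than 1e-10 min to avoid zero-length segments
  keep <- c(TRUE, diff(tt) > 1e-10)
  tt <- tt[keep]
  list(t = tt, p = curve_interp(cp, tt))
}

#' Forward model: tissue curve for given rate constants and input
#'
#' Solves the model ODEs `dCf/dt = K1*Cp - (k2+k3)*Cf`, `dCb/dt = k3*Cf`
#' against a piecewise-linear plasma free-leucine input `Cp`, using the
#' closed form
#' `CT(t) = Kcplx*int_0^t Cp + (K1*k2/(k2+k3)) * int_0^t exp(-(k2+k3)(t-s)) Cp(s) ds`
#' with every input segment's convolution integrated exactly (no ODE-solver
#' step-size error).
#'
#' @param rc A [rate_constants()] object.
#' @param cp Plasma free-leucine input as a [sampled_curve()]; must cover
#'   `[0, max(eval_times)]`.
#' @param eval_times Times (min) at which to return the tissue curve.
#' @return A tissue [sampled_curve()] with extra columns `cf` (free pool)
#'   and `cb` (protein-bound pool); `value = cf + cb`.
#' @examples
#' cp <- sampled_curve(seq(0, 60, 0.5), rep(100, 121), role = "plasma_free")
#' ct <- solve_model(rate_constants(0.05, 0.1, 0.05), cp, c(1, 10, 60))
#' @export
solve_model <- function(rc, cp, eval_times) {
  rc <- as_rc(rc)
  eval_times <- sort(as.numeric(eval_times))
  if (any(eval_times < 0)) stop("evaluation times must be >= 0.", call. = FALSE)
  a <- rc$k2 + rc$k3
  kc <- compute_kcplx(rc)
  kn <- conv_knots(cp, eval_times)
  tabs <- conv_tables(kn$t, kn$p, a)
  idx <- match(round(eval_times, 10), round(kn$t, 10))
  cf <- rc$K1 * tabs$E[idx]
  cb <- kc * tabs$I[idx] - (rc$k3 / a) * cf
  out <- curve_update(as_leu_curve(cp), time_min = eval_times,
                      value = cf + cb, role = "tissue")
  out$cf <- cf
  out$cb <- cb
  out
}

#' Exact per-frame means of the model tissue curve
#'
#' Frame averages of the forward model, computed analytically (the frame
#' integral of the convolution has a closed form for a piecewise-linear
#' input), optionally mixed with a fixed fractional blood-volume term
#' `vb * Cwb`. This is the quantity the fit compares to measured frame
#' values, and the quantity the synthetic generator perturbs with noise.
#'
#' @inheritParams solve_model
#' @param schedule A [frame_schedule()].
#' @param vb Fractional blood volume (default 0 = plain tissue model).
#' @param wb Whole-blood curve, required when `vb > 0`.
#' @return Numeric vector of exact frame means.
#' @export
solve_model_frames <- function(rc, cp, schedule, vb = 0, wb = NULL) {
  rc <- as_rc(rc)
  eng <- frame_engine(cp, schedule)
  mu <- engine_frames(eng, rc$K1, rc$k2, rc$k3)
  if (vb > 0) {
    if (is.null(wb)) {
      stop("a blood-volume term requires a whole-blood curve `wb`.",
           call. = FALSE)
    }
    mu <- (1 - vb) * mu + vb * frame_average(wb, schedule)
  }
  mu
}

# Precompute everything parameter-independent for repeated frame-mean
# evaluations against one input/schedule pair (the fit's inner loop).
frame_engine <- function(cp, schedule) {
  edges <- sort(unique(c(schedule$start_min, schedule$end_min)))
  kn <- conv_knots(cp, edges)
  idx <- match(round(edges, 10), round(kn$t, 10))
  list(
    tt = kn$t, pp = kn$p, idx = idx,
    i0 = match(round(schedule$start_min, 10), round(edges, 10)),
    i1 = match(round(schedule$end_min, 10), round(edges, 10)),
    dur = schedule$dur_min
  )
}

engine_frames <- function(eng, K1, k2, k3) {
  a <- k2 + k3
  kc <- K1 * k3 / a
  tabs <- conv_tables(eng$tt, eng$pp, a, want_JF = TRUE)
  # int_0^t CT = Kcplx*J + (K1*k2/a)*F
  ct_int <- kc * tabs$J[eng$idx] + (K1 * k2 / a) * tabs$F[eng$idx]
  (ct_int[eng$i1] - ct_int[eng$i0]) / eng$dur
}

fit_weights <- function(schedule, weighting = c("duration_decay", "uniform")) {
  weighting <- match.arg(weighting)
  w <- switch(weighting,
    duration_decay = schedule$dur_min * exp(-C11_LAMBDA * schedule$mid_min),
    uniform = rep(1, nrow(schedule))
  )
  w / mean(w)
}

default_fit_bounds <- function() {
  list(lower = c(K1 = 1e-5, k2 = 1e-5, k3 = 1e-5),
       upper = c(K1 = 2, k2 = 5, k3 = 5))
}

# Deterministic 3x3x3 log-spaced multistart grid strictly inside the bounds.
multistart_grid <- function(bounds = default_fit_bounds(), n = 3) {
  axis <- function(lo, hi) {
    g <- exp(seq(log(lo), log(hi), length.out = n + 2))
    g[-c(1, n + 2)]
  }
  grid <- expand.grid(
    K1 = axis(bounds$lower[["K1"]], bounds$upper[["K1"]]),
    k2 = axis(bounds$lower[["k2"]], bounds$upper[["k2"]]),
    k3 = axis(bounds$lower[["k3"]], bounds$upper[["k3"]]),
    KEEP.OUT.ATTRS = FALSE
  )
  tibble::as_tibble(grid)
}

#' Fit the three rate constants to a measured tissue TAC
#'
#' Weighted nonlinear least squares of the per-frame model means against the
#' measured frame values, by Levenberg-Marquardt with box bounds from a
#' deterministic log-spaced multistart grid (best weighted residual sum of
#' squares wins; ties broken by smallest K1). Derived quantities lambda,
#' Kcplx and (when `leu` is supplied) PSR are computed from the estimates.
#'
#' @param tac Measured per-frame tissue activity: a numeric vector with one
#'   value per frame, or a data frame with an `activity` column.
#' @param schedule A [frame_schedule()] matching `tac`.
#' @param cp Plasma free-leucine input function as a [sampled_curve()].
#' @param leu Unlabelled arterial plasma leucine, nmol/ml; `NA` skips PSR.
#' @param weighting `"duration_decay"` (default; weight = frame duration x
#'   physical-decay factor at the frame mid-time, approximating
#'   uncorrected-count variance) or `"uniform"`.
#' @param bounds List with named `lower`/`upper` vectors for K1, k2, k3.
#' @param starts Data frame of start points (columns K1, k2, k3); default
#'   the 3x3x3 log-spaced grid inside `bounds`.
#' @param vb Fractional blood volume for an optional `vb * Cwb` term
#'   (default 0, i.e. the plain model); requires `wb` when positive.
#' @param wb Whole-blood curve, only used when `vb > 0`.
#' @param ptol Relative parameter tolerance for convergence.
#' @param maxit Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `leu_fit`: see [tidy.leu_fit()],
#'   [glance.leu_fit()], [autoplot.leu_fit()].
#' @examples
#' cp <- sampled_curve(seq(0, 60, 0.25),
#'                     1000 * seq(0, 60, 0.25) * exp(-seq(0, 60, 0.25)),
#'                     role = "plasma_free")
#' sch <- default_frame_schedule()
#' truth <- rate_constants(0.05, 0.1, 0.05)
#' tac <- solve_model_frames(truth, cp, sch)
#' fit <- fit_rate_constants(tac, sch, cp, leu = 228)
#' tidy(fit)
#' @export
fit_rate_constants <- function(tac, schedule, cp, leu = NA_real_,
                               weighting = c("duration_decay", "uniform"),
                               bounds = default_fit_bounds(),
                               starts = NULL, vb = 0, wb = NULL,
                               ptol = 1e-8, maxit = 500) {
  if (is.data.frame(tac)) {
    if (!"activity" %in% names(tac)) {
      stop("`tac` data frame needs an `activity` column.", call. = FALSE)
    }
    tac <- tac$activity
  }
  tac <- as.numeric(tac)
  if (length(tac) != nrow(schedule)) {
    stop("`tac` must have one value per frame of `schedule`.", call. = FALSE)
  }
  if (nrow(schedule) < 8L) {
    stop("at least 8 frames are required to fit three rate constants.",
         call. = FALSE)
  }
  if (all(tac == 0) || sum(tac * schedule$dur_min) <= 0) {
    stop("no signal: tissue TAC is all zero or has non-positive integral.",
         call. = FALSE)
  }
  weighting <- match.arg(weighting)
  w <- fit_weights(schedule, weighting)
  sw <- sqrt(w)
  starts <- starts %||% multistart_grid(bounds)

  eng <- frame_engine(cp, schedule)
  wb_frames <- if (vb > 0) {
    if (is.null(wb)) {
      stop("a blood-volume term requires a whole-blood curve `wb`.",
           call. = FALSE)
    }
    frame_average(wb, schedule)
  }
  resid_fun <- function(par) {
    mu <- engine_frames(eng, par[1], par[2], par[3])
    if (vb > 0) mu <- (1 - vb) * mu + vb * wb_frames
    sw * (tac - mu)
  }

  lower <- bounds$lower[c("K1", "k2", "k3")]
  upper <- bounds$upper[c("K1", "k2", "k3")]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(as.numeric(starts[s, c("K1", "k2", "k3")]), lower),
                 upper)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper, fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          ptol = ptol, ftol = ptol, maxiter = maxit)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    wrss <- sum(res$fvec^2)
    converged <- res$info %in% 1:4
    cand <- list(par = res$par, wrss = wrss, converged = converged,
                 start = s, niter = res$niter, hessian = res$hessian)
    if (is.null(best) ||
        cand$wrss < best$wrss - 1e-12 * max(1, best$wrss) ||
        (abs(cand$wrss - best$wrss) <= 1e-12 * max(1, best$wrss) &&
         cand$par[1] < best$par[1])) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("optimizer failed from every start point.", call. = FALSE)
  }
  if (!best$converged) {
    warning("fit did not formally converge from its best start; ",
            "inspect diagnostics before using the estimates.", call. = FALSE)
  }

  est <- rate_constants(best$par[1], best$par[2], best$par[3])
  lambda_ <- compute_lambda(est)
  kcplx <- compute_kcplx(est)
  psr <- if (is.finite(leu)) compute_psr(kcplx, lambda_, leu) else NA_real_

  vcov_par <- tryCatch({
    dof <- length(tac) - 3L
    s2 <- best$wrss / max(dof, 1L)
    s2 * solve(best$hessian)
  }, error = function(e) NULL)

  structure(list(
    estimates = est,
    lambda = lambda_,
    kcplx = kcplx,
    psr = psr,
    leu = leu,
    wrss = best$wrss,
    n_frames = length(tac),
    converged = best$converged,
    start_used = best$start,
    niter = best$niter,
    vcov = vcov_par,
    weighting = weighting,
    vb = vb,
    tac = tac,
    schedule = schedule,
    cp = cp,
    wb = wb
  ), class = "leu_fit")
}

#' @export
print.leu_fit <- function(x, ...) {
  cat("Irreversible two-tissue leucine model fit\n")
  cat(sprintf("  K1 = %.5f ml/ml/min, k2 = %.5f 1/min, k3 = %.5f 1/min\n",
              x$estimates$K1, x$estimates$k2, x$estimates$k3))
  cat(sprintf("  lambda = %.4f, Kcplx = %.5f 1/min", x$lambda, x$kcplx))
  if (is.finite(x$psr)) {
    cat(sprintf(", PSR = %.3f nmol/ml/min (leu = %.1f nmol/ml)",
                x$psr, x$leu))
  }
  cat(sprintf("\n  WRSS = %.4g over %d frames; converged: %s\n",
              x$wrss, x$n_frames, x$converged))
  invisible(x)
}

# Patlak coordinates with frame-consistent averaging: the tissue values
# are frame means, so Cp and its running integral are frame-averaged too
# (mid-point sampling of Cp against frame-mean CT biases the slope on
# late, long frames).
patlak_coords <- function(tac, schedule, cp) {
  edges <- sort(unique(c(schedule$start_min, schedule$end_min)))
  kn <- conv_knots(cp, edges)
  tabs <- conv_tables(kn$t, kn$p, a = 1, want_JF = TRUE)
  idx <- match(round(edges, 10), round(kn$t, 10))
  i0 <- match(round(schedule$start_min, 10), round(edges, 10))
  i1 <- match(round(schedule$end_min, 10), round(edges, 10))
  cp_bar <- (tabs$I[idx][i1] - tabs$I[idx][i0]) / schedule$dur_min
  int_bar <- (tabs$J[idx][i1] - tabs$J[idx][i0]) / schedule$dur_min
  tibble::tibble(mid_min = schedule$mid_min,
                 x = int_bar / cp_bar, y = tac / cp_bar, cp_bar = cp_bar)
}

#' Patlak graphical analysis of an irreversible tracer
#'
#' Ordinary least-squares slope of frame-mean `CT/Cp` against the
#' normalized time `int_0^t Cp / Cp` over frames with mid-time at or after
#' `t_start` (both coordinates frame-averaged, matching the frame-mean
#' tissue data). For an irreversibly trapped tracer the asymptotic slope
#' equals the trapping rate Kcplx, making this a model-independent
#' cross-check of the compartmental fit.
#'
#' @inheritParams fit_rate_constants
#' @param t_start Start of the linear window, min (>= 10; default 20, when
#'   the free pool has equilibrated for typical rat leucine kinetics).
#' @return The Patlak slope, min^-1.
#' @export
patlak_slope <- function(tac, schedule, cp, t_start = 20) {
  if (is.data.frame(tac)) tac <- tac$activity
  if (t_start < 10) {
    stop("`t_start` must be >= 10 min for the Patlak asymptote.",
         call. = FALSE)
  }
  use <- schedule$mid_min >= t_start - 1e-9
  if (sum(use) < 4L) {
    stop("at least 4 frames after `t_start` are required.", call. = FALSE)
  }
  coords <- patlak_coords(tac, schedule, cp)[use, ]
  if (any(coords$cp_bar <= 0)) {
    stop("input function is non-positive at a frame used by the Patlak plot.",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(y ~ x, data = coords))[2])
}
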