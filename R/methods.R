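#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a compartmental model fit
#'
#' One row per parameter (K1, k2, k3) with standard errors from the
#' Levenberg-Marquardt covariance when available.
#'
#' @param x A `leu_fit` from [fit_rate_constants()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.leu_fit <- function(x, ...) {
  se <- rep(NA_real_, 3)
  if (!is.null(x$vcov)) {
    d <- diag(x$vcov)
    se <- ifelse(d >= 0, sqrt(d), NA_real_)
  }
  tibble::tibble(
    term = c("K1", "k2", "k3"),
    estimate = c(x$estimates$K1, x$estimates$k2, x$estimates$k3),
    std.error = se
  )
}

#' One-row summary of a compartmental model fit
#'
#' @param x A `leu_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the derived quantities and diagnostics.
#' @export
glance.leu_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, Kcplx = x$kcplx, PSR = x$psr, leu = x$leu,
    wrss = x$wrss, n_frames = x$n_frames, converged = x$converged,
    niter = x$niter, weighting = x$weighting
  )
}

#' Plot a fit: measured frames and the fitted model curve
#'
#' @param object A `leu_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.leu_fit <- function(object, ...) {
  sch <- object$schedule
  obs <- tibble::tibble(time_min = sch$mid_min, value = object$tac)
  grid <- seq(0, max(sch$end_min), length.out = 241)
  fitted <- solve_model(object$estimates, object$cp, grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_line(data = tibble::tibble(time_min = fitted$time_min,
                                             value = fitted$value),
                       colour = "firebrick") +
    ggplot2::labs(x = "Time (min)", y = "Activity (Bq/ml)",
                  title = sprintf(
                    "Kcplx = %.4f 1/min, lambda = %.3f%s",
                    object$kcplx, object$lambda,
                    if (is.finite(object$psr)) {
                      sprintf(", PSR = %.2f nmol/ml/min", object$psr)
                    } else ""))
}

#' Plot any sampled curve
#'
#' @param object A [sampled_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.leu_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)",
                  y = sprintf("%s (%s)", curve_role(object),
                              attr(object, "units") %||% "Bq/ml"))
}

#' Bland-Altman style plot of an input-function agreement report
#'
#' @param object A [compare_if_methods()] report.
#' @param ... Unused.
#' @return A ggplot of paired differences by region with the limits of
#'   agreement.
#' @export
autoplot.leu_agreement <- function(object, ...) {
  paired <- attr(object, "paired")
  paired$mean_pair <- (paired$aif + paired$pbif) / 2
  paired$diff <- paired$pbif - paired$aif
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$mean_pair, y = .data$diff,
                                       colour = .data$region)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_hline(data = tibble::as_tibble(object),
                        ggplot2::aes(yintercept = .data$loa_lower,
                                     colour = .data$region),
                        linetype = 3) +
    ggplot2::geom_hline(data = tibble::as_tibble(object),
                        ggplot2::aes(yintercept = .data$loa_upper,
                                     colour = .data$region),
                        linetype = 3) +
    ggplot2::labs(x = "Mean of paired PSR", y = "PBIF - AIF difference")
}

#' Plot a Patlak linearization
#'
#' @param tac Per-frame tissue values.
#' @param schedule A [frame_schedule()].
#' @param cp Input function.
#' @param t_start Linear-window start, min.
#' @return A ggplot of the Patlak coordinates and the fitted line.
#' @export
plot_patlak <- function(tac, schedule, cp, t_start = 20) {
  if (is.data.frame(tac)) tac <- tac$activity
  coords <- patlak_coords(tac, schedule, cp)
  dat <- tibble::tibble(x = coords$x, y = coords$y,
                        used = coords$mid_min >= t_start)
  slope <- patlak_slope(tac, schedule, cp, t_start)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    shape = .data$used)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(data = dat[dat$used, ], method = "lm",
                         formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(x = "Normalized time  int Cp / Cp  (min)",
                  y = "CT / Cp",
                  title = sprintf("Patlak slope = %.5f 1/min", slope))
}
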