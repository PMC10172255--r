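# Half-away-from-zero rounding for printed-style integer percentages
# (base round() is banker's rounding).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent difference relative to a reference value
#'
#' `100 * (other - reference) / reference`. Tables print the half-away-
#' from-zero integer rounding; full precision is retained unless
#' `rounded = TRUE`.
#'
#' @param reference Reference value (non-zero).
#' @param other Comparison value.
#' @param rounded Return the integer-rounded value.
#' @return Percent difference.
#' @examples
#' percent_difference(231, 162)            # -29.87...
#' percent_difference(231, 162, rounded = TRUE)  # -30
#' @export
percent_difference <- function(reference, other, rounded = FALSE) {
  if (any(reference == 0)) {
    stop("reference value must be non-zero.", call. = FALSE)
  }
  pd <- 100 * (other - reference) / reference
  if (rounded) round_half_away(pd) else pd
}

#' Percent inhibition of a rate relative to baseline
#'
#' `100 * (1 - treated / baseline)`; equals the negated
#' [percent_difference()].
#'
#' @param baseline Baseline rate (> 0).
#' @param treated Treated rate.
#' @param rounded Return the integer-rounded value.
#' @return Percent inhibition.
#' @examples
#' percent_inhibition(5.25, 0.81)  # 84.57...
#' @export
percent_inhibition <- function(baseline, treated, rounded = FALSE) {
  if (any(baseline <= 0)) {
    stop("baseline must be positive.", call. = FALSE)
  }
  pi_ <- 100 * (1 - treated / baseline)
  if (rounded) round_half_away(pi_) else pi_
}

#' Group summary table (mean, SD, n)
#'
#' Mean +/- SD descriptive summaries per group, in deterministic
#' (alphabetical) group order. Groups of size one get `sd = 0` with
#' `sd_defined = FALSE` rather than `NA`, so downstream tables stay numeric
#' but the degenerate case stays visible.
#'
#' @param data A data frame of per-subject results (e.g. bound
#'   [region_result()] rows).
#' @param value Name of the numeric column to summarize (string).
#' @param by Character vector of grouping columns.
#' @return A tibble with the grouping columns plus `mean`, `sd`, `n`,
#'   `sd_defined`.
#' @export
summarize_groups <- function(data, value, by) {
  if (!nrow(data)) stop("no rows to summarize.", call. = FALSE)
  missing_cols <- setdiff(c(value, by), names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sd = ifelse(dplyr::n() > 1L, stats::sd(.data[[value]]), 0),
      n = dplyr::n(),
      sd_defined = dplyr::n() > 1L,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
}

#' One study-result row per subject x region x timepoint
#'
#' @param subject,region Identifiers.
#' @param genotype,age_months,arm Study labels (arm: e.g. `"baseline"`,
#'   `"anisomycin"`).
#' @param fit A `leu_fit` (or `NULL`).
#' @param suv_value Regional SUV over the 20-60 min window.
#' @return A one-row tibble with K1, k2, k3, lambda, Kcplx, PSR, wrss,
#'   converged, suv.
#' @export
region_result <- function(subject, region, genotype = NA_character_,
                          age_months = NA_real_, arm = "baseline",
                          fit = NULL, suv_value = NA_real_) {
  base <- tibble::tibble(
    subject = as.character(subject), region = as.character(region),
    genotype = genotype, age_months = age_months, arm = arm,
    K1 = NA_real_, k2 = NA_real_, k3 = NA_real_, lambda = NA_real_,
    Kcplx = NA_real_, PSR = NA_real_, wrss = NA_real_, converged = NA,
    suv = suv_value
  )
  if (!is.null(fit)) {
    base$K1 <- fit$estimates$K1
    base$k2 <- fit$estimates$k2
    base$k3 <- fit$estimates$k3
    base$lambda <- fit$lambda
    base$Kcplx <- fit$kcplx
    base$PSR <- fit$psr
    base$wrss <- fit$wrss
    base$converged <- fit$converged
  }
  base
}

#' Agreement report between two input-function methods
#'
#' Pairs results by subject x region and reports, per region, the mean
#' difference, mean relative difference (relative to the reference
#' arterial-sampling values), Bland-Altman 95% limits of agreement and the
#' sign balance. This is a descriptive report; any formal hypothesis test
#' belongs to a standard statistics environment downstream.
#'
#' @param aif_results,pbif_results Data frames with columns `subject`,
#'   `region` and `value` (e.g. PSR computed with individual AIFs vs with
#'   the scaled PBIF).
#' @return A tibble of class `leu_agreement`, one row per region:
#'   `n`, `mean_diff`, `mean_rel_diff`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `n_positive`, `n_negative`.
#' @export
compare_if_methods <- function(aif_results, pbif_results) {
  need <- c("subject", "region", "value")
  if (!all(need %in% names(aif_results)) ||
      !all(need %in% names(pbif_results))) {
    stop("both inputs need columns subject, region, value.", call. = FALSE)
  }
  paired <- dplyr::full_join(
    dplyr::select(aif_results, "subject", "region", aif = "value"),
    dplyr::select(pbif_results, "subject", "region", pbif = "value"),
    by = c("subject", "region")
  )
  orphans <- paired[!stats::complete.cases(paired[, c("aif", "pbif")]), ]
  if (nrow(orphans)) {
    stop("unpaired rows: ",
         paste(sprintf("%s/%s", orphans$subject, orphans$region),
               collapse = ", "), call. = FALSE)
  }
  out <- paired |>
    dplyr::mutate(diff = .data$pbif - .data$aif,
                  rel_diff = .data$diff / .data$aif) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_diff = mean(.data$diff),
      mean_rel_diff = mean(.data$rel_diff),
      sd_diff = ifelse(dplyr::n() > 1, stats::sd(.data$diff), 0),
      loa_lower = .data$mean_diff - 1.96 * .data$sd_diff,
      loa_upper = .data$mean_diff + 1.96 * .data$sd_diff,
      n_positive = sum(.data$diff > 0),
      n_negative = sum(.data$diff < 0),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$region)
  class(out) <- c("leu_agreement", class(out))
  attr(out, "paired") <- paired
  out
}

#' Write an agreement report as TSV and JSON
#'
#' @param report A [compare_if_methods()] result.
#' @param path_tsv,path_json Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_agreement <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    readr::write_tsv(tibble::as_tibble(report), path_tsv)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(tibble::as_tibble(report), path_json,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
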