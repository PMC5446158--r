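#' Area under a 12-month FP curve
#'
#' Trapezoidal rule on the month index (unit spacing, no extrapolation
#' beyond January or December), i.e. `sum((v[i] + v[i+1]) / 2)` over the
#' eleven month-to-month intervals. On the percent-cover scale the result
#' is in percent-cover-months; a curve pinned at 100% all year has volume
#' 1100.
#'
#' @param fp_by_month Numeric vector of exactly 12 ordered monthly FP
#'   values (January..December), finite and non-negative.
#' @return The flowering volume (scalar).
#' @export
trapezoid_auc <- function(fp_by_month) {
  if (length(fp_by_month) != 12L) {
    stop("expected 12 monthly values, got ", length(fp_by_month),
         call. = FALSE)
  }
  if (any(!is.finite(fp_by_month)) || any(fp_by_month < 0)) {
    stop("FP values must be finite and non-negative", call. = FALSE)
  }
  pracma::trapz(1:12, fp_by_month)
}

#' Per-plot flowering volumes from a total-community FP matrix
#'
#' @param fp A total-community [fp_matrix()] result covering months 1..12.
#' @return Tibble with the plot key columns and `volume_pct_month`, the
#'   area under the plot's FP curve on the percent scale.
#' @export
flowering_volumes <- function(fp) {
  if (!all(1:12 %in% fp$month)) {
    stop("flowering volume needs all 12 months of FP", call. = FALSE)
  }
  fp |>
    dplyr::arrange(.data$month) |>
    dplyr::summarise(
      volume_pct_month = trapezoid_auc(100 * .data$fp),
      .by = dplyr::all_of(PLOT_KEY))
}
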