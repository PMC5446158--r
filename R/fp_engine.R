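SUBSET_KINDS <- c("total", "provenance", "functional_group")

#' Specify a community subset for FP computation
#'
#' FP profiles are computed for the total community and, with the same
#' relative covers (no re-normalisation within the subset), for provenance
#' and functional-group subsets; a subset profile is therefore the fraction
#' of total community cover held by that subset's flowering species.
#'
#' @param kind One of `"total"`, `"provenance"`, `"functional_group"`.
#' @param value Subset label: a provenance (`"native"`, `"exotic"`) or a
#'   functional group (`"C3_graminoid"`, `"C4_graminoid"`, `"forb"`,
#'   `"legume"`, `"woody"`, `"other"`). Must be omitted for `kind = "total"`.
#' @return A `subset_spec` object.
#' @export
subset_spec <- function(kind = "total", value = NULL) {
  kind <- match.arg(kind, SUBSET_KINDS)
  if (kind == "total") {
    if (!is.null(value)) stop("'total' takes no subset value", call. = FALSE)
    value <- ""
  } else {
    allowed <- if (kind == "provenance") c("native", "exotic")
               else FUNCTIONAL_GROUPS
    if (is.null(value) || !value %in% allowed) {
      stop("subset value for kind '", kind, "' must be one of: ",
           paste(allowed, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(kind = kind, value = value), class = "subset_spec")
}

#' @export
print.subset_spec <- function(x, ...) {
  cat("FP subset:", if (x$kind == "total") "total community"
      else paste0(x$kind, " = ", x$value), "\n")
  invisible(x)
}

# 0/1 membership of each catalog taxon in a subset.
.subset_indicator <- function(catalog, subset) {
  switch(subset$kind,
    total = rep(1, nrow(catalog)),
    provenance = as.numeric(catalog$provenance == subset$value),
    functional_group = as.numeric(catalog$functional_group == subset$value))
}

#' Flowering potential of one plot in one month
#'
#' The FP statistic: the summed relative cover of those species in the plot
#' whose published flowering interval includes the month (restricted to the
#' subset if one is given). Each species' relative cover is multiplied by a
#' 0/1 monthly flowering weight and the weighted values are summed over the
#' plot.
#'
#' @param composition Tibble of one plot's observations carrying `taxon`
#'   and `rel_cover` (from [relativize()]).
#' @param catalog Trait catalog; every taxon in `composition` must have an
#'   entry (exclusions are upstream).
#' @param month Month index in 1..12.
#' @param subset A [subset_spec()]; default total community.
#' @return FP value on the proportion scale, in \[0, 1\].
#' @export
monthly_fp <- function(composition, catalog, month,
                       subset = subset_spec("total")) {
  stopifnot(length(month) == 1L, month %in% 1:12)
  idx <- match(composition$taxon, catalog$taxon)
  if (anyNA(idx)) {
    stop("taxon without trait record (exclude upstream): ",
         paste(unique(composition$taxon[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  w <- flowering_weight_matrix(catalog)[idx, month]
  s <- .subset_indicator(catalog, subset)[idx]
  sum(composition$rel_cover * w * s)
}

#' Plot-by-month FP matrix for one subset
#'
#' Computes FP for every plot and all 12 calendar months (months outside
#' the growing season are retained so the flowering-volume curve spans
#' January-December).
#'
#' @param compositions Relativized observations for any number of plots
#'   (output of [relativize()]).
#' @param catalog Trait catalog.
#' @param subset A [subset_spec()].
#' @return Tidy tibble: plot key columns, `month` (1..12), `fp`
#'   (proportion scale), plus `subset_kind` and `subset_value`.
#' @export
fp_matrix <- function(compositions, catalog, subset = subset_spec("total")) {
  idx <- match(compositions$taxon, catalog$taxon)
  if (anyNA(idx)) {
    stop("taxon without trait record (exclude upstream): ",
         paste(unique(compositions$taxon[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  W <- flowering_weight_matrix(catalog) *
    .subset_indicator(catalog, subset)   # zero weights outside the subset
  contrib <- compositions$rel_cover * W[idx, , drop = FALSE]
  plots <- dplyr::distinct(compositions, dplyr::across(dplyr::all_of(PLOT_KEY)))
  pid <- match(
    do.call(paste, c(compositions[PLOT_KEY], sep = "\r")),
    do.call(paste, c(plots[PLOT_KEY], sep = "\r")))
  fp <- rowsum(contrib, group = pid, reorder = TRUE)
  out <- tidyr::expand_grid(plots, month = 1:12)
  out$fp <- as.vector(t(fp))
  out$subset_kind <- subset$kind
  out$subset_value <- subset$value
  out
}

#' Long-format FP table over several subsets
#'
#' @param compositions Relativized observations.
#' @param catalog Trait catalog.
#' @param subsets List of [subset_spec()] objects; defaults to the profiles
#'   reported for prairie communities (total, exotic, native, forb, C3 and
#'   C4 graminoids, legume).
#' @return Row-bound [fp_matrix()] tibbles with `fp_pct = 100 * fp`.
#' @export
fp_long <- function(compositions, catalog, subsets = default_subsets()) {
  out <- dplyr::bind_rows(
    lapply(subsets, function(s) fp_matrix(compositions, catalog, s)))
  out$fp_pct <- 100 * out$fp
  out
}

#' @rdname fp_long
#' @export
default_subsets <- function() {
  list(subset_spec("total"),
       subset_spec("provenance", "exotic"),
       subset_spec("provenance", "native"),
       subset_spec("functional_group", "forb"),
       subset_spec("functional_group", "C3_graminoid"),
       subset_spec("functional_group", "C4_graminoid"),
       subset_spec("functional_group", "legume"))
}

#' Treatment-group FP profiles (mean +/- SE)
#'
#' Summarises an FP matrix into the figure-style profiles: for each
#' ecoregion, month and nitrogen group (N_added pools the four +N factorial
#' combinations, N_free the four without N), the mean and standard error of
#' plot FP on the percent scale.
#'
#' @param fp An [fp_matrix()] result.
#' @param months Months to report (default growing season, May-October).
#' @return Tibble `ecoregion, month, group, mean_fp_pct, se_fp_pct, n`;
#'   SE is `NA` when a group holds a single plot.
#' @export
group_profiles <- function(fp, months = 5:10) {
  stopifnot(all(months %in% 1:12))
  fp |>
    dplyr::filter(.data$month %in% months) |>
    dplyr::mutate(group = ifelse(.data$trt_N, "N_added", "N_free")) |>
    dplyr::summarise(
      mean_fp_pct = 100 * mean(.data$fp),
      se_fp_pct = if (dplyr::n() >= 2L)
        100 * stats::sd(.data$fp) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .by = c("ecoregion", "month", "group")) |>
    tidyr::complete(.data$ecoregion, month = months,
                    group = c("N_added", "N_free"),
                    fill = list(n = 0L)) |>
    dplyr::arrange(.data$ecoregion, .data$month, .data$group)
}
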