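.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.sig6 <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
}

.subset_tag <- function(s) if (s$kind == "total") "total" else s$value

#' Write a synthetic dataset to disk
#'
#' Generates the configured synthetic cover survey and trait catalog and
#' writes `cover.csv`, `traits.csv`, `truth.json` (injected-effect ground
#' truth plus the full configuration, seed included) and `manifest.json`
#' into the output directory.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- .stage("simulate", simulate_dataset(config))
  paths <- c(cover = file.path(out_dir, "cover.csv"),
             traits = file.path(out_dir, "traits.csv"),
             truth = file.path(out_dir, "truth.json"),
             manifest = file.path(out_dir, "manifest.json"))
  .stage("write", {
    write_cover(sim$cover, paths[["cover"]])
    write_trait_catalog(sim$catalog, paths[["traits"]])
    jsonlite::write_json(
      list(truth = sim$truth, config = unclass(config)),
      paths[["truth"]], auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = config$seed, n_plots = nrow(sim$design),
           n_taxa = nrow(sim$catalog), n_observations = nrow(sim$cover),
           files = as.list(basename(paths[1:3]))),
      paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  })
  message("simulate: wrote ", nrow(sim$cover), " observations, ",
          nrow(sim$catalog), " taxa to ", out_dir)
  invisible(paths)
}

#' Run the full flowering-potential analysis
#'
#' Orchestrates the pipeline on a cover survey and trait catalog: load and
#' validate, apply the exclusion rules, relativize within plots, compute
#' FP for the requested subsets, fit the growing-season mixed model and
#' nitrogen-by-month Bonferroni contrasts per subset, compute per-plot
#' flowering volumes and the volume mixed model, and write all result
#' tables (floating point at 6 significant digits) plus a run summary.
#' A subset whose mixed model cannot be fitted (e.g. a structurally
#' constant FP) is recorded as a warning in the summary, not an abort.
#'
#' @param cover_csv,trait_csv Input file paths.
#' @param out_dir Output directory.
#' @param months Growing-season months for the FP model (default May-Oct).
#' @param subsets List of [subset_spec()]s (default [default_subsets()]).
#' @param by_ecoregion Contrast mode: pooled (`FALSE`) or per ecoregion.
#' @param alpha Significance level recorded in the summary.
#' @return Named list of written file paths, invisibly.
#' @export
run_analyze <- function(cover_csv, trait_csv, out_dir,
                        months = 5:10, subsets = default_subsets(),
                        by_ecoregion = FALSE, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, all(months %in% 1:12),
            all(diff(sort(months)) == 1L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  catalog <- .stage("load traits",
                    suppressMessages(load_trait_catalog(trait_csv)))
  cover <- .stage("load cover", suppressMessages(load_cover(cover_csv)))
  excl <- .stage("exclusions",
                 suppressMessages(apply_exclusions(cover, catalog)))
  if (nrow(excl$report) > 0L) {
    warnings_log <- c(warnings_log,
                      sprintf("excluded %d taxa (%d rows)",
                              nrow(excl$report), sum(excl$report$n_rows)))
  }
  comp <- .stage("relativize", relativize(excl$included))
  fp <- .stage("fp", fp_long(comp, catalog, subsets))
  paths <- list(exclusions = file.path(out_dir, "exclusions.csv"),
                fp_long = file.path(out_dir, "fp_long.csv"))
  readr::write_csv(.sig6(excl$report), paths$exclusions)
  readr::write_csv(
    .sig6(fp[, c(PLOT_KEY, "subset_kind", "subset_value", "month",
                 "fp_pct")]),
    paths$fp_long)
  for (s in subsets) {
    tag <- .subset_tag(s)
    sub_fp <- fp[fp$subset_kind == s$kind & fp$subset_value == s$value, ]
    res <- tryCatch({
      fit <- fit_fp_lmm(sub_fp, months = months)
      list(anova = anova_table(fit),
           contrasts = n_by_month_contrasts(fit, by_ecoregion))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      warnings_log <- c(warnings_log,
                        sprintf("subset '%s': %s", tag, res))
      next
    }
    paths[[paste0("anova_", tag)]] <-
      file.path(out_dir, paste0("anova_", tag, ".csv"))
    paths[[paste0("contrasts_", tag)]] <-
      file.path(out_dir, paste0("contrasts_", tag, ".csv"))
    readr::write_csv(.sig6(res$anova), paths[[paste0("anova_", tag)]])
    readr::write_csv(.sig6(res$contrasts),
                     paths[[paste0("contrasts_", tag)]])
  }
  total_fp <- fp[fp$subset_kind == "total", ]
  vol <- .stage("volume", flowering_volumes(total_fp))
  paths$volume <- file.path(out_dir, "volume.csv")
  readr::write_csv(.sig6(vol), paths$volume)
  vol_res <- tryCatch(fit_volume_lmm(vol), error = function(e)
    conditionMessage(e))
  if (is.character(vol_res)) {
    warnings_log <- c(warnings_log, paste0("volume model: ", vol_res))
  } else {
    paths$anova_volume <- file.path(out_dir, "anova_volume.csv")
    readr::write_csv(.sig6(vol_res$anova), paths$anova_volume)
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("phenofp")),
    inputs = list(cover = cover_csv, traits = trait_csv),
    months = months, alpha = alpha, by_ecoregion = by_ecoregion,
    subsets = vapply(subsets, .subset_tag, character(1)),
    n_observations = nrow(cover), n_plots = nrow(
      dplyr::distinct(cover, dplyr::across(dplyr::all_of(PLOT_KEY)))),
    mean_volume_pct_month = mean(vol$volume_pct_month),
    se_volume_pct_month = stats::sd(vol$volume_pct_month) /
      sqrt(nrow(vol)),
    warnings = warnings_log)
  paths$summary <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA)
  message("analyze: wrote ", length(paths), " files to ", out_dir,
          if (length(warnings_log)) paste0(" (", length(warnings_log),
                                           " warning(s) in summary)") else "")
  invisible(paths)
}

#' Simulate-then-analyze convenience wrapper
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (simulated inputs and results).
#' @param ... Passed to [run_analyze()].
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir, ...) {
  sim_paths <- run_simulate(config, out_dir)
  res <- run_analyze(sim_paths[["cover"]], sim_paths[["traits"]],
                     out_dir, ...)
  invisible(c(as.list(sim_paths), res))
}
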