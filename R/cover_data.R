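ECOREGIONS <- c("tallgrass", "mixedgrass", "shortgrass")

# Columns identifying one plot; treatment flags and ecoregion ride along.
PLOT_KEY <- c("site", "ecoregion", "block", "plot", "trt_N", "trt_P", "trt_K")

#' Load a plot-level percent-cover survey table
#'
#' Reads a cover CSV with columns `site, ecoregion, block, plot, trt_N,
#' trt_P, trt_K, taxon, cover_pct` (NutNet-style; header required, UTF-8).
#' Cover is absolute percent cover as surveyed at peak biomass; because
#' canopies overlap, a plot's covers may total more than 100%. Zero-cover
#' rows are not allowed (absence is encoded by the row being absent).
#'
#' @param path Path to the cover CSV.
#' @return A tibble of validated observations; treatment flags as logicals,
#'   `cover_pct` numeric in (0, 100].
#' @export
load_cover <- function(path) {
  required <- c(PLOT_KEY, "taxon", "cover_pct")
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("cover table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  obs <- tibble::tibble(
    site = raw$site,
    ecoregion = raw$ecoregion,
    block = raw$block,
    plot = raw$plot,
    trt_N = .parse_flag(raw$trt_N, "trt_N"),
    trt_P = .parse_flag(raw$trt_P, "trt_P"),
    trt_K = .parse_flag(raw$trt_K, "trt_K"),
    taxon = raw$taxon,
    cover_pct = suppressWarnings(as.numeric(raw$cover_pct))
  )
  validate_cover(obs)
  n_plots <- nrow(dplyr::distinct(obs, dplyr::across(dplyr::all_of(PLOT_KEY))))
  message("cover table: ", nrow(obs), " observations across ",
          n_plots, " plots")
  obs
}

.parse_flag <- function(x, name) {
  lut <- c("true" = TRUE, "t" = TRUE, "1" = TRUE, "yes" = TRUE,
           "false" = FALSE, "f" = FALSE, "0" = FALSE, "no" = FALSE)
  out <- lut[tolower(trimws(x))]
  if (anyNA(out)) {
    stop("column ", name, " has unparseable treatment flag(s) at row(s) ",
         paste(head(which(is.na(out)), 5L), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Validate cover observations
#'
#' Checks the invariants of the survey dialect: numeric cover in (0, 100],
#' known ecoregion labels, and uniqueness of (site, block, plot, taxon).
#'
#' @param obs Cover observation tibble.
#' @return `obs`, invisibly, if valid; otherwise an error naming offending
#'   rows.
#' @export
validate_cover <- function(obs) {
  bad_num <- which(is.na(obs$cover_pct))
  if (length(bad_num) > 0L) {
    stop("non-numeric cover_pct at row(s) ",
         paste(head(bad_num, 5L), collapse = ", "), call. = FALSE)
  }
  out_rng <- which(obs$cover_pct <= 0 | obs$cover_pct > 100)
  if (length(out_rng) > 0L) {
    stop("cover_pct outside (0, 100] at row(s) ",
         paste(head(out_rng, 5L), collapse = ", "),
         " (zero-cover rows must be omitted)", call. = FALSE)
  }
  bad_eco <- which(!obs$ecoregion %in% ECOREGIONS)
  if (length(bad_eco) > 0L) {
    stop("unknown ecoregion at row(s) ",
         paste(head(bad_eco, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(obs$site, obs$block, obs$plot, obs$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (site, block, plot, taxon) at row(s) ",
         paste(head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(obs)
}

#' Apply the analysis exclusion rules to cover observations
#'
#' Removes observations whose taxon is identified only to genus, is a tree
#' seedling, or has no trait record at all; these cannot carry a flowering
#' interval and are dropped before relative cover is computed. Idempotent.
#'
#' @param obs Cover observation tibble.
#' @param catalog Trait catalog from [load_trait_catalog()].
#' @return A list with `included` (the surviving observations) and `report`,
#'   a tibble `taxon, reason, n_rows, total_cover` with one row per excluded
#'   taxon (empty when nothing was excluded).
#' @export
apply_exclusions <- function(obs, catalog) {
  idx <- match(obs$taxon, catalog$taxon)
  reason <- rep(NA_character_, nrow(obs))
  reason[is.na(idx)] <- "no trait record"
  known <- !is.na(idx)
  lf <- catalog$lifeform[idx[known]]
  reason[known][lf == "genus_only_placeholder"] <- "genus-only"
  reason[known][lf == "tree_seedling"] <- "tree seedling"
  drop <- !is.na(reason)
  report <- tibble::tibble(taxon = obs$taxon[drop],
                           reason = reason[drop],
                           cover = obs$cover_pct[drop]) |>
    dplyr::summarise(n_rows = dplyr::n(),
                     total_cover = sum(.data$cover),
                     .by = c("taxon", "reason")) |>
    dplyr::arrange(.data$taxon)
  included <- obs[!drop, , drop = FALSE]
  if (nrow(report) > 0L) {
    message("exclusions: dropped ", sum(drop), " row(s) across ",
            nrow(report), " taxa")
  }
  if (nrow(included) == 0L) {
    warning("no observations remain after exclusions", call. = FALSE)
  }
  list(included = included, report = report)
}

#' Convert absolute percent cover to relative cover within plots
#'
#' Divides each species' cover by its plot's total cover, so the analysed
#' composition sums to one per plot even where overlapping canopies push
#' the absolute total past 100%. Exclusions are expected to have been
#' applied first, so relative cover is over analysable taxa only.
#'
#' @param obs Cover observation tibble (post-exclusion).
#' @return The observations with an added `rel_cover` column on the
#'   proportion scale; within every plot `sum(rel_cover) == 1`.
#' @export
relativize <- function(obs) {
  if (nrow(obs) == 0L) {
    stop("cannot relativize a plot with no vegetated cover", call. = FALSE)
  }
  dplyr::mutate(obs, rel_cover = .data$cover_pct / sum(.data$cover_pct),
                .by = dplyr::all_of(PLOT_KEY))
}

#' Derive the 8-level treatment combination label
#'
#' @param trt_N,trt_P,trt_K Logical treatment flags.
#' @return Character vector with labels in
#'   \{control, N, P, K+u, NP, NK+u, PK+u, NPK+u\}.
#' @export
treatment_label <- function(trt_N, trt_P, trt_K) {
  lab <- paste0(ifelse(trt_N, "N", ""), ifelse(trt_P, "P", ""),
                ifelse(trt_K, "K+u", ""))
  ifelse(lab == "", "control", lab)
}

#' Write cover observations to the survey CSV dialect
#'
#' @param obs Cover observation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cover <- function(obs, path) {
  readr::write_csv(obs[, c(PLOT_KEY, "taxon", "cover_pct")], path)
  invisible(path)
}
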