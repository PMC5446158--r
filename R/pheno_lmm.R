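#' @importFrom stats model.matrix as.formula pt terms delete.response
NULL

# Sum-to-zero coded factors so marginal (each-term-last) F tests are
# well-defined; on the balanced factorial they coincide with sequential.
.lmm_factor <- function(x, levels) {
  f <- factor(x, levels = levels)
  if (length(levels) >= 2L) {
    stats::contrasts(f) <- stats::contr.sum(length(levels))
  }
  f
}

.prep_lmm_data <- function(df, with_month = TRUE, months = 5:10) {
  eco_levels <- intersect(ECOREGIONS, unique(df$ecoregion))
  out <- tibble::tibble(
    site = factor(df$site),
    block = factor(df$block),
    P = .lmm_factor(ifelse(df$trt_P, "added", "ambient"),
                    c("ambient", "added")),
    K = .lmm_factor(ifelse(df$trt_K, "added", "ambient"),
                    c("ambient", "added")),
    N = .lmm_factor(ifelse(df$trt_N, "added", "ambient"),
                    c("ambient", "added")),
    ecoregion = .lmm_factor(df$ecoregion, eco_levels)
  )
  if (with_month) {
    out$month <- .lmm_factor(month.abb[df$month], month.abb[months])
  }
  out
}

.check_design <- function(dat, factors) {
  for (f in factors) {
    n_lev <- length(unique(as.character(dat[[f]])))
    if (n_lev < 2L) {
      stop("degenerate design: factor '", f, "' has ", n_lev,
           " observed level(s); the factorial mixed model needs >= 2",
           call. = FALSE)
    }
  }
}

#' Fit the flowering-potential linear mixed model
#'
#' Fits, for one FP subset, the growing-season model with full factorial
#' fixed effects for phosphorus, potassium(+micronutrients), nitrogen,
#' month (May-October) and ecoregion, and random intercepts for site and
#' block nested within site. Estimation is by REML; factors are
#' sum-to-zero coded. Monthly FP values from the same plot enter as
#' independent residuals (no plot-level random effect), a deliberate
#' pseudo-replication caveat documented in the methods vignette.
#'
#' @param fp_sub Long FP table for a single subset, with plot key columns,
#'   `month` and `fp_pct` (e.g. one subset slice of [fp_long()]).
#' @param months Growing-season month indices modelled (default May-Oct).
#' @return An object of class `fp_lmm`: a list carrying the `nlme::lme`
#'   fit, the prepared data, and the model formula.
#' @export
fit_fp_lmm <- function(fp_sub, months = 5:10) {
  stopifnot(all(months %in% 1:12), length(months) >= 2L)
  if ("subset_kind" %in% names(fp_sub) &&
      nrow(dplyr::distinct(fp_sub, .data$subset_kind, .data$subset_value)) > 1L) {
    stop("fit_fp_lmm expects FP values for a single subset", call. = FALSE)
  }
  fp_sub <- dplyr::filter(fp_sub, .data$month %in% months)
  dat <- .prep_lmm_data(fp_sub, with_month = TRUE, months = months)
  dat$fp_pct <- if ("fp_pct" %in% names(fp_sub)) fp_sub$fp_pct
                else 100 * fp_sub$fp
  .check_design(dat, c("P", "K", "N", "month", "ecoregion"))
  if (stats::sd(dat$fp_pct) == 0) {
    stop("degenerate response: FP is constant across all observations",
         call. = FALSE)
  }
  form <- fp_pct ~ P * K * N * month * ecoregion
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | site / block, data = dat,
              method = "REML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
    error = function(e) {
      stop("mixed-model fit failed (singular or deficient design?): ",
           conditionMessage(e), call. = FALSE)
    })
  structure(list(fit = fit, data = dat, formula = form,
                 months = months, method = "REML",
                 response = "fp_pct"),
            class = "fp_lmm")
}

#' @export
print.fp_lmm <- function(x, ...) {
  cat("Flowering-potential mixed model (", x$method, ")\n", sep = "")
  cat("  fixed:  ", deparse(x$formula), "\n")
  cat("  random: ~1 | site/block;  n =", nrow(x$data), "obs\n")
  invisible(x)
}

# Canonical fixed-effect term order: by interaction degree; within a
# degree, nutrient-only terms, then terms with Month, then with Ecoregion,
# then with both; nutrient subsets in P < K < N combination order.
.term_order <- function(with_month = TRUE) {
  elems <- c("P", "K", "N", if (with_month) "month", "ecoregion")
  subsets <- unlist(lapply(seq_along(elems), function(k)
    utils::combn(elems, k, simplify = FALSE)), recursive = FALSE)
  key <- vapply(subsets, function(s) {
    sig <- ("month" %in% s) + 2L * ("ecoregion" %in% s)
    nut <- match(intersect(c("P", "K", "N"), s), c("P", "K", "N"))
    sprintf("%02d-%d-%s", length(s), sig,
            paste(sprintf("%d", c(nut, rep(9L, 3 - length(nut)))),
                  collapse = ""))
  }, character(1))
  vapply(subsets[order(key)], paste, character(1), collapse = ":")
}

.pretty_term <- function(term) {
  lut <- c("(Intercept)" = "Intercept", "P" = "P", "K" = "K+u", "N" = "N",
           "month" = "Month", "ecoregion" = "Ecoregion")
  vapply(strsplit(term, ":", fixed = TRUE),
         function(parts) paste(lut[parts], collapse = " * "), character(1))
}

#' Fixed-effect ANOVA table of a fitted mixed model
#'
#' Marginal (each-term-last) F tests under sum-to-zero coding, one row per
#' fixed-effect term in the canonical factorial order (main effects, then
#' interactions grouped by degree), with numerator and containment-style
#' denominator degrees of freedom.
#'
#' @param model An `fp_lmm` or `volume_lmm` object.
#' @param type `"marginal"` (default) or `"sequential"` F tests.
#' @return Tibble `term, ndf, ddf, F, p`.
#' @export
anova_table <- function(model, type = c("marginal", "sequential")) {
  type <- match.arg(type)
  stopifnot(inherits(model, c("fp_lmm", "volume_lmm")))
  a <- stats::anova(model$fit, type = type)
  raw_terms <- rownames(a)
  ord <- c("(Intercept)", .term_order(with_month = "month" %in% raw_terms))
  a <- a[match(ord, raw_terms), ]
  tibble::tibble(term = .pretty_term(ord),
                 ndf = a$numDF, ddf = a$denDF,
                 F = a[["F-value"]], p = a[["p-value"]])
}

# Model matrix over the full factor grid, sharing the fit's contrasts.
.reference_grid <- function(model) {
  dat <- model$data
  cols <- intersect(c("P", "K", "N", "month", "ecoregion"), names(dat))
  grid <- expand.grid(lapply(dat[cols], function(f)
    factor(levels(f), levels = levels(f))), KEEP.OUT.ATTRS = FALSE)
  for (co in cols) stats::contrasts(grid[[co]]) <- stats::contrasts(dat[[co]])
  rhs <- stats::reformulate(attr(terms(model$formula), "term.labels"))
  list(grid = grid, X = model.matrix(rhs, grid))
}

#' Nitrogen contrasts by month with Bonferroni correction
#'
#' Model-based mean FP difference between nitrogen-added plots (N, NP,
#' NK+u, NPK+u) and nitrogen-free plots (control, P, K+u, PK+u) for each
#' growing-season month, averaged over the phosphorus and potassium levels
#' (and over ecoregions when pooled). Each raw p is multiplied by the
#' family size m -- all contrasts produced by the call (6 pooled, 18 by
#' ecoregion for three ecoregions) -- and capped at 1.
#'
#' @param model An `fp_lmm` object.
#' @param by_ecoregion If `TRUE`, one contrast per ecoregion x month;
#'   otherwise pooled over ecoregions.
#' @return Tibble `ecoregion, month, estimate, SE, df, t, p_raw, p_adj, m,
#'   stars`; `estimate` is N_added minus N_free on the percent scale.
#' @export
n_by_month_contrasts <- function(model, by_ecoregion = FALSE) {
  stopifnot(inherits(model, "fp_lmm"))
  rg <- .reference_grid(model)
  beta <- nlme::fixef(model$fit)
  V <- stats::vcov(model$fit)
  # N varies within block, so its contrasts sit at the residual stratum
  ddf <- model$fit$fixDF$terms[["N"]]
  months <- levels(model$data$month)
  strata <- if (by_ecoregion) levels(model$data$ecoregion) else "pooled"
  rows <- expand.grid(month = months, ecoregion = strata,
                      stringsAsFactors = FALSE)
  est <- se <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    sel <- rg$grid$month == rows$month[i]
    if (by_ecoregion) sel <- sel & rg$grid$ecoregion == rows$ecoregion[i]
    L <- colMeans(rg$X[sel & rg$grid$N == "added", , drop = FALSE]) -
         colMeans(rg$X[sel & rg$grid$N == "ambient", , drop = FALSE])
    est[i] <- sum(L * beta)
    se[i] <- sqrt(drop(t(L) %*% V %*% L))
  }
  m <- nrow(rows)
  t_stat <- est / se
  p_raw <- 2 * pt(-abs(t_stat), df = ddf)
  p_adj <- bonferroni_adjust(p_raw, m)
  tibble::tibble(ecoregion = rows$ecoregion,
                 month = match(rows$month, month.abb),
                 estimate = est, SE = se, df = ddf, t = t_stat,
                 p_raw = p_raw, p_adj = p_adj, m = m,
                 stars = significance_stars(p_adj))
}

#' Bonferroni adjustment
#'
#' @param p Raw p-values.
#' @param m Family size (number of simultaneous contrasts).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Significance stars on adjusted p-values
#'
#' @param p Adjusted p-values.
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   otherwise `""`.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Fit the flowering-volume mixed model
#'
#' Models per-plot January-December flowering volume with factorial
#' phosphorus x potassium x nitrogen x ecoregion fixed effects (no month
#' term) and random intercepts for site and block within site.
#'
#' @param volumes Output of [flowering_volumes()].
#' @return An object of class `volume_lmm` (same shape as `fp_lmm`) with
#'   an `anova` element holding the fixed-effect table.
#' @export
fit_volume_lmm <- function(volumes) {
  dat <- .prep_lmm_data(volumes, with_month = FALSE)
  dat$volume_pct_month <- volumes$volume_pct_month
  .check_design(dat, c("P", "K", "N", "ecoregion"))
  if (stats::sd(dat$volume_pct_month) == 0) {
    stop("degenerate response: flowering volume is constant across plots",
         call. = FALSE)
  }
  form <- volume_pct_month ~ P * K * N * ecoregion
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | site / block, data = dat,
              method = "REML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
    error = function(e) {
      stop("volume mixed-model fit failed: ", conditionMessage(e),
           call. = FALSE)
    })
  out <- structure(list(fit = fit, data = dat, formula = form,
                        months = 1:12, method = "REML",
                        response = "volume_pct_month"),
                   class = "volume_lmm")
  out$anova <- anova_table(out)
  out
}

#' @export
print.volume_lmm <- function(x, ...) {
  cat("Flowering-volume mixed model (", x$method, ")\n", sep = "")
  cat("  fixed:  ", deparse(x$formula), "\n")
  cat("  random: ~1 | site/block;  n =", nrow(x$data), "plots\n")
  invisible(x)
}
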