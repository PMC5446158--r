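# Shared in-code fixtures; nothing is read from disk except files the
# tests themselves write to tempdir().

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# A small hand-built catalog: a June-August forb (the worked-example
# phenology), an early exotic C3 graminoid, a late native C4 graminoid,
# a legume, plus a genus-only placeholder and a tree seedling.
tiny_catalog <- function() {
  quietly(build_trait_catalog(tibble::tibble(
    taxon = c("Monarda fistulosa", "Bromus inermis", "Andropogon gerardii",
              "Dalea purpurea", "Carex sp.", "Quercus macrocarpa seedling"),
    flowering_months = list(6:8, 5:6, 8:10, 6:7, 5:7, 5L),
    provenance = c("native", "exotic", "native", "native", "unknown",
                   "native"),
    functional_group = c("forb", "C3_graminoid", "C4_graminoid", "legume",
                         "other", "woody"),
    lifeform = c("herbaceous", "herbaceous", "herbaceous", "herbaceous",
                 "genus_only_placeholder", "tree_seedling"),
    source = "test fixture")))
}

# One block of 8 factorial plots at a single site, two species per plot.
tiny_cover <- function() {
  trt <- expand.grid(trt_N = c(FALSE, TRUE), trt_P = c(FALSE, TRUE),
                     trt_K = c(FALSE, TRUE))
  dplyr::bind_rows(lapply(1:8, function(i) tibble::tibble(
    site = "tg_site01", ecoregion = "tallgrass", block = "b1",
    plot = paste0("p", i),
    trt_N = trt$trt_N[i], trt_P = trt$trt_P[i], trt_K = trt$trt_K[i],
    taxon = c("Monarda fistulosa", "Andropogon gerardii"),
    cover_pct = c(40 + i, 60 - i))))
}

# Random catalog + single-plot composition used by brute-force oracles.
random_catalog <- function(n_species, all_known_provenance = TRUE) {
  groups <- c("C3_graminoid", "C4_graminoid", "forb", "legume")
  tibble::tibble(
    taxon = sprintf("Testus species%03d", seq_len(n_species)),
    flowering_months = lapply(seq_len(n_species), function(i) {
      start <- sample(1:12, 1)
      len <- sample(1:5, 1)
      sort(unique(((start:(start + len - 1) - 1) %% 12) + 1))
    }),
    provenance = sample(c("native", "exotic"), n_species, replace = TRUE),
    functional_group = sample(groups, n_species, replace = TRUE),
    lifeform = "herbaceous",
    source = "test fixture",
    includable = TRUE)
}

random_composition <- function(catalog, plot = "p1") {
  cov <- stats::runif(nrow(catalog), 0.5, 30)
  tibble::tibble(site = "s1", ecoregion = "tallgrass", block = "b1",
                 plot = plot, trt_N = FALSE, trt_P = FALSE, trt_K = FALSE,
                 taxon = catalog$taxon, cover_pct = cov,
                 rel_cover = cov / sum(cov))
}

# Independent brute-force FP oracle: explicit species x month double loop.
fp_brute_force <- function(composition, catalog, subset_kind = "total",
                           subset_value = "") {
  sapply(1:12, function(m) {
    tot <- 0
    for (i in seq_len(nrow(composition))) {
      j <- which(catalog$taxon == composition$taxon[i])
      flowers <- m %in% catalog$flowering_months[[j]]
      in_sub <- switch(subset_kind,
        total = TRUE,
        provenance = catalog$provenance[j] == subset_value,
        functional_group = catalog$functional_group[j] == subset_value)
      if (flowers && in_sub) tot <- tot + composition$rel_cover[i]
    }
    tot
  })
}

# One simulated dataset pushed through the pipeline to pooled or
# by-ecoregion N contrasts.
simulate_and_contrast <- function(config, by_ecoregion = FALSE) {
  sim <- simulate_dataset(config)
  ex <- quietly(apply_exclusions(sim$cover, sim$catalog))
  fp <- fp_matrix(relativize(ex$included), sim$catalog)
  fp$fp_pct <- 100 * fp$fp
  fit <- fit_fp_lmm(fp)
  n_by_month_contrasts(fit, by_ecoregion = by_ecoregion)
}

null_config <- function(seed) {
  synthetic_config(
    seed = seed,
    n_sites = c(tallgrass = 1L, mixedgrass = 1L, shortgrass = 1L),
    n_blocks = 2L,
    effect_N_early_exotic = 1, effect_N_early_C3 = 1, effect_N_late_C4 = 1)
}
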