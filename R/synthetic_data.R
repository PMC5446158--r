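#' Configuration for the synthetic NutNet-style generator
#'
#' Defines the simulated study conditions: a factorial NPK(+micronutrient)
#' design replicated in blocks within sites, sites grouped into three
#' prairie ecoregions, ecoregion-specific species pools with flowering
#' windows concentrated in the growing season (C4 graminoids skewed late,
#' C3 graminoids and exotics earlier), long-tailed baseline abundances,
#' overlapping canopies (plot totals above 100%), and a known nitrogen
#' effect structure used by recovery tests: under added N the expected
#' absolute cover of early-flowering exotics and C3 graminoids is scaled
#' up and that of late-flowering C4 graminoids scaled down, in the
#' configured ecoregions only. Because effects act on absolute cover, the
#' compositional trade-off (C3 up implies C4 relatively down) emerges from
#' relativization rather than being hard-coded.
#'
#' @param seed Integer RNG seed (all generator randomness flows from it).
#' @param n_sites Named integer vector of sites per ecoregion.
#' @param n_blocks Blocks per site.
#' @param species_pool_size Includable species per ecoregion pool.
#' @param exotic_fraction Probability a pool species is exotic.
#' @param group_mix Named proportions over functional groups.
#' @param n_placeholders Genus-only placeholder taxa per ecoregion
#'   (plus one tree seedling), present in plots but excluded by the
#'   analysis rules.
#' @param window_length_probs Probabilities for flowering-window lengths
#'   1..4 months.
#' @param baseline_concentration Gamma shape for baseline abundance
#'   weights (values below 1 give strongly long-tailed communities).
#' @param effect_N_early_exotic,effect_N_early_C3 Multiplier on expected
#'   cover under added N for exotics / C3 graminoids flowering in May or
#'   June.
#' @param effect_N_late_C4 Multiplier under added N for C4 graminoids
#'   flowering in September or October.
#' @param effect_ecoregions Ecoregions in which the N effects act.
#' @param noise_sd Log-scale SD of multiplicative plot-to-plot cover noise.
#' @param total_cover_range Range the absolute plot cover total is drawn
#'   from (percent; above 100 exercises the canopy-overlap path).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_sites = c(tallgrass = 3L, mixedgrass = 2L, shortgrass = 3L),
    n_blocks = 3L,
    species_pool_size = 40L,
    exotic_fraction = 0.25,
    group_mix = c(forb = 0.40, C3_graminoid = 0.20, C4_graminoid = 0.20,
                  legume = 0.10, woody = 0.10),
    n_placeholders = 2L,
    window_length_probs = c(0.20, 0.35, 0.30, 0.15),
    baseline_concentration = 0.7,
    effect_N_early_exotic = 1.8,
    effect_N_early_C3 = 1.6,
    effect_N_late_C4 = 0.6,
    effect_ecoregions = "tallgrass",
    noise_sd = 0.4,
    total_cover_range = c(80, 160)) {
  cfg <- list(seed = as.integer(seed), n_sites = n_sites,
              n_blocks = as.integer(n_blocks),
              species_pool_size = as.integer(species_pool_size),
              exotic_fraction = exotic_fraction, group_mix = group_mix,
              n_placeholders = as.integer(n_placeholders),
              window_length_probs = window_length_probs,
              baseline_concentration = baseline_concentration,
              effect_N_early_exotic = effect_N_early_exotic,
              effect_N_early_C3 = effect_N_early_C3,
              effect_N_late_C4 = effect_N_late_C4,
              effect_ecoregions = effect_ecoregions,
              noise_sd = noise_sd, total_cover_range = total_cover_range)
  stopifnot(
    cfg$seed >= 0L, cfg$seed <= .Machine$integer.max - 1L,
    all(names(cfg$n_sites) %in% ECOREGIONS), all(cfg$n_sites >= 1L),
    cfg$n_blocks >= 1L, cfg$species_pool_size >= 1L,
    cfg$exotic_fraction >= 0, cfg$exotic_fraction <= 1,
    cfg$n_placeholders >= 0L, cfg$n_placeholders <= 2L,
    abs(sum(cfg$group_mix) - 1) < 1e-9,
    all(names(cfg$group_mix) %in% FUNCTIONAL_GROUPS),
    length(cfg$window_length_probs) == 4L,
    abs(sum(cfg$window_length_probs) - 1) < 1e-9,
    cfg$baseline_concentration > 0,
    cfg$effect_N_early_exotic > 0, cfg$effect_N_early_C3 > 0,
    cfg$effect_N_late_C4 > 0,
    all(cfg$effect_ecoregions %in% ECOREGIONS) ||
      length(cfg$effect_ecoregions) == 0L,
    cfg$noise_sd >= 0,
    length(cfg$total_cover_range) == 2L,
    cfg$total_cover_range[1] > 0, diff(cfg$total_cover_range) >= 0)
  structure(cfg, class = "synthetic_config")
}

#' Field-scale preset of the synthetic configuration
#'
#' Eleven sites split 6 tallgrass / 2 mixedgrass / 3 shortgrass, as in the
#' field network the generator emulates; other settings as
#' [synthetic_config()].
#'
#' @param seed Integer RNG seed.
#' @param ... Further overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_config_field_scale <- function(seed = 1L, ...) {
  synthetic_config(seed = seed,
                   n_sites = c(tallgrass = 6L, mixedgrass = 2L,
                               shortgrass = 3L), ...)
}

#' Build the complete crossed plot design
#'
#' Every block contains exactly the eight NPK(+micronutrient) factorial
#' treatment combinations; ecoregion is assigned at site level. The design
#' is deterministic given the configuration (no randomness involved).
#'
#' @param config A [synthetic_config()].
#' @return Tibble with one row per plot: `site, ecoregion, block, plot,
#'   trt_N, trt_P, trt_K`.
#' @export
make_design <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  eco_code <- c(tallgrass = "tg", mixedgrass = "mg", shortgrass = "sg")
  sites <- dplyr::bind_rows(lapply(names(config$n_sites), function(eco) {
    tibble::tibble(
      site = sprintf("%s_site%02d", eco_code[[eco]],
                     seq_len(config$n_sites[[eco]])),
      ecoregion = eco)
  }))
  trt <- expand.grid(trt_N = c(FALSE, TRUE), trt_P = c(FALSE, TRUE),
                     trt_K = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE)
  design <- tidyr::expand_grid(
    sites, block = sprintf("b%d", seq_len(config$n_blocks)),
    plot_idx = 1:8)
  design <- dplyr::bind_cols(design, trt[design$plot_idx, ])
  design$plot <- sprintf("p%d", design$plot_idx)
  design$plot_idx <- NULL
  tibble::as_tibble(design[, PLOT_KEY])
}

# Flowering-window start distributions by phenology guild, mirroring
# prairie phenology: cool-season (C3) graminoids and exotics flower early
# (May-June), most native forbs/legumes mid-to-late summer, warm-season
# (C4) graminoids late (August-October).
.window_start <- function(n, guild) {
  switch(guild,
    early = sample(4:7, n, replace = TRUE, prob = c(0.30, 0.40, 0.20, 0.10)),
    mid = sample(6:9, n, replace = TRUE, prob = c(0.20, 0.35, 0.30, 0.15)),
    late = sample(7:10, n, replace = TRUE, prob = c(0.20, 0.35, 0.30, 0.15)))
}

.phenology_guild <- function(functional_group, provenance) {
  ifelse(functional_group == "C4_graminoid", "late",
         ifelse(functional_group == "C3_graminoid" | provenance == "exotic",
                "early", "mid"))
}

#' Generate ecoregion species pools with traits and baseline abundances
#'
#' Samples, per ecoregion, a pool of species with functional group,
#' provenance, a 1-4 month flowering window (windows of C4 graminoids are
#' centred later in the season than those of other species), a long-tailed
#' baseline abundance weight, and the nitrogen cover multiplier implied by
#' the configured effect structure. A few genus-only placeholders and one
#' tree seedling per ecoregion carry cover but are flagged non-includable.
#' Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with the trait-catalog columns plus `ecoregion`,
#'   `baseline_weight`, `n_multiplier` and `includable`.
#' @export
make_species_pool <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  eco_code <- c(tallgrass = "TG", mixedgrass = "MG", shortgrass = "SG")
  pools <- lapply(names(config$n_sites), function(eco) {
    n <- config$species_pool_size
    fg <- sample(names(config$group_mix), n, replace = TRUE,
                 prob = config$group_mix)
    prov <- ifelse(stats::runif(n) < config$exotic_fraction,
                   "exotic", "native")
    guild <- .phenology_guild(fg, prov)
    start <- integer(n)
    for (g in c("early", "mid", "late")) {
      start[guild == g] <- .window_start(sum(guild == g), g)
    }
    len <- sample(1:4, n, replace = TRUE, prob = config$window_length_probs)
    months <- lapply(seq_len(n), function(i)
      seq.int(start[i], min(12L, start[i] + len[i] - 1L)))
    w <- stats::rgamma(n, shape = config$baseline_concentration, rate = 1)
    sp <- tibble::tibble(
      taxon = sprintf("Synthetica %s%03d", tolower(eco_code[[eco]]),
                      seq_len(n)),
      flowering_months = months,
      provenance = prov,
      functional_group = fg,
      lifeform = "herbaceous",
      source = "synthetic pool",
      ecoregion = eco,
      baseline_weight = w)
    ph <- tibble::tibble(
      taxon = c(sprintf("Carex sp. (%s)", eco_code[[eco]]),
                sprintf("Juncus sp. (%s)", eco_code[[eco]]),
                sprintf("Quercus seedling (%s)", eco_code[[eco]]))[
                  seq_len(config$n_placeholders + 1L)],
      flowering_months = rep(list(5:7), config$n_placeholders + 1L),
      provenance = "unknown",
      functional_group = "other",
      lifeform = c(rep("genus_only_placeholder", config$n_placeholders),
                   "tree_seedling"),
      source = "synthetic pool",
      ecoregion = eco,
      baseline_weight = stats::rgamma(config$n_placeholders + 1L,
                                      shape = config$baseline_concentration,
                                      rate = 1) * 0.2)
    dplyr::bind_rows(sp, ph)
  })
  pool <- dplyr::bind_rows(pools)
  pool$includable <- !(pool$lifeform %in% c("genus_only_placeholder",
                                            "tree_seedling"))
  pool$n_multiplier <- .n_multiplier(pool, config)
  pool
}

# Nitrogen multiplier on expected absolute cover for one species.
# Early = flowers in May or June; late = flowers in September or October.
# Exotic status takes precedence over the C3 pathway for early species.
.n_multiplier <- function(pool, config) {
  early <- vapply(pool$flowering_months,
                  function(m) any(m %in% 5:6), logical(1))
  late <- vapply(pool$flowering_months,
                 function(m) any(m %in% 9:10), logical(1))
  mult <- rep(1, nrow(pool))
  up <- early & pool$includable
  mult[up & pool$provenance == "exotic"] <- config$effect_N_early_exotic
  mult[up & pool$provenance != "exotic" &
         pool$functional_group == "C3_graminoid"] <- config$effect_N_early_C3
  down <- late & pool$includable & pool$functional_group == "C4_graminoid"
  mult[down] <- mult[down] * config$effect_N_late_C4
  mult[!pool$ecoregion %in% config$effect_ecoregions] <- 1
  mult
}

#' Extract the trait catalog from a species pool
#'
#' @param pool Output of [make_species_pool()].
#' @return A trait catalog tibble as produced by [build_trait_catalog()].
#' @export
pool_catalog <- function(pool) {
  build_trait_catalog(pool[, c("taxon", "flowering_months", "provenance",
                               "functional_group", "lifeform", "source")])
}

#' Analytic ground truth of the injected nitrogen effect
#'
#' The expected N_added minus N_free total-FP difference per ecoregion and
#' month, computed from the configured multipliers and the pool's baseline
#' composition (the zero-noise limit of the simulation): under each
#' nitrogen level the expected relative cover of species i is
#' `w_i m_i / sum_j w_j m_j` over includable species, and the FP
#' difference for a month sums those differences across species flowering
#' then. Identically zero when all multipliers are 1.
#'
#' @param pool Output of [make_species_pool()].
#' @return Tibble `ecoregion, month, fp_diff_pct` (percent scale).
#' @export
synthetic_truth <- function(pool) {
  inc <- pool[pool$includable, , drop = FALSE]
  out <- lapply(split(inc, inc$ecoregion), function(p) {
    w <- p$baseline_weight
    rel0 <- w / sum(w)
    relN <- (w * p$n_multiplier) / sum(w * p$n_multiplier)
    diff_pct <- vapply(1:12, function(m) {
      fl <- vapply(p$flowering_months, function(fm) m %in% fm, logical(1))
      100 * sum((relN - rel0)[fl])
    }, numeric(1))
    tibble::tibble(ecoregion = p$ecoregion[1], month = 1:12,
                   fp_diff_pct = diff_pct)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$ecoregion, .data$month)
}

#' Simulate cover observations for a design and species pool
#'
#' Every includable and placeholder species of a plot's ecoregion pool is
#' present in the plot; its expected absolute cover is the baseline weight
#' times the nitrogen multiplier (when N is added in an effect ecoregion),
#' perturbed by log-normal noise, and the plot's covers are rescaled so
#' the absolute total lands at a draw from `total_cover_range` (capped at
#' 100% per species). Deterministic given `config$seed`: the RNG stream is
#' seeded with `seed + 1` so pool and cover draws never overlap.
#'
#' @param design Output of [make_design()].
#' @param pool Output of [make_species_pool()].
#' @param config The same [synthetic_config()].
#' @return A list: `cover` (observation tibble accepted by
#'   [validate_cover()]) and `truth` (see [synthetic_truth()]).
#' @export
simulate_cover <- function(design, pool, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    p <- pool[pool$ecoregion == design$ecoregion[i], , drop = FALSE]
    mult <- if (design$trt_N[i]) p$n_multiplier else rep(1, nrow(p))
    raw <- p$baseline_weight * mult *
      exp(stats::rnorm(nrow(p), 0, config$noise_sd))
    total <- stats::runif(1, config$total_cover_range[1],
                          config$total_cover_range[2])
    cover <- pmin(100, raw / sum(raw) * total)
    tibble::tibble(design[i, PLOT_KEY], taxon = p$taxon,
                   cover_pct = round(cover, 6))
  })
  cover <- dplyr::bind_rows(rows)
  cover <- cover[cover$cover_pct > 0, , drop = FALSE]
  validate_cover(cover)
  list(cover = cover, truth = synthetic_truth(pool))
}

#' One-call synthetic dataset
#'
#' @param config A [synthetic_config()].
#' @return List with `design`, `pool`, `catalog`, `cover`, `truth`,
#'   `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  design <- make_design(config)
  pool <- make_species_pool(config)
  sim <- simulate_cover(design, pool, config)
  list(design = design, pool = pool,
       catalog = suppressMessages(pool_catalog(pool)),
       cover = sim$cover, truth = sim$truth, config = config)
}
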