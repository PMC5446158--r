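test_that("the design is a complete crossed factorial", {
  d <- make_design(synthetic_config())
  expect_equal(nrow(d), 8L * 3L * 8L)   # 8 sites x 3 blocks x 8 combos

  d1 <- make_design(synthetic_config(
    n_sites = c(tallgrass = 1L, mixedgrass = 1L, shortgrass = 1L),
    n_blocks = 1L))
  expect_equal(nrow(d1), 24L)

  combos <- dplyr::summarise(
    d, n = dplyr::n(),
    n_trt = nrow(unique(cbind(trt_N, trt_P, trt_K))),
    .by = c(site, block))
  expect_true(all(combos$n == 8L & combos$n_trt == 8L))

  dp <- make_design(synthetic_config_field_scale())
  expect_equal(length(unique(dp$site)), 11L)
  expect_equal(sum(dp$ecoregion == "tallgrass"), 6L * 3L * 8L)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 99, n_sites = c(tallgrass = 1L),
                          n_blocks = 1L)
  p1 <- make_species_pool(cfg)
  p2 <- make_species_pool(cfg)
  expect_identical(p1, p2)

  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$cover, s2$cover)
  expect_identical(s1$truth, s2$truth)

  f1 <- file.path(tempdir(), "det1.csv")
  f2 <- file.path(tempdir(), "det2.csv")
  write_cover(s1$cover, f1)
  write_cover(s2$cover, f2)
  expect_identical(readLines(f1), readLines(f2))

  s3 <- simulate_dataset(synthetic_config(seed = 100,
                                          n_sites = c(tallgrass = 1L),
                                          n_blocks = 1L))
  expect_false(identical(s1$cover$cover_pct, s3$cover$cover_pct))
})

test_that("the injected truth is zero iff all multipliers are one", {
  null_pool <- make_species_pool(null_config(7))
  tr <- synthetic_truth(null_pool)
  expect_true(all(tr$fp_diff_pct == 0))

  eff_pool <- make_species_pool(synthetic_config(seed = 7))
  tr_eff <- synthetic_truth(eff_pool)
  expect_true(any(tr_eff$fp_diff_pct != 0))
  # effects confined to the configured ecoregion
  expect_true(all(tr_eff$fp_diff_pct[tr_eff$ecoregion != "tallgrass"] == 0))
})

test_that("pools respect configured label proportions and windows", {
  cfg <- synthetic_config(seed = 13, species_pool_size = 10000L,
                          n_sites = c(tallgrass = 1L))
  pool <- make_species_pool(cfg)
  sp <- pool[pool$includable, ]

  lens <- vapply(sp$flowering_months, length, integer(1))
  # window lengths 1..4; truncation at December can only shorten, and is
  # rare, so compare against the configured distribution with MC slack
  emp <- tabulate(lens, 4) / nrow(sp)
  expect_true(all(abs(emp - cfg$window_length_probs) < 0.02))
  expect_true(all(lens >= 1L & lens <= 4L))

  expect_equal(mean(sp$provenance == "exotic"), cfg$exotic_fraction,
               tolerance = 0.03)
  emp_mix <- table(factor(sp$functional_group,
                          levels = names(cfg$group_mix))) / nrow(sp)
  expect_true(all(abs(as.numeric(emp_mix) - cfg$group_mix) < 0.02))

  # C4 windows sit later in the season than C3 windows
  mid <- vapply(sp$flowering_months, mean, numeric(1))
  expect_gt(mean(mid[sp$functional_group == "C4_graminoid"]),
            mean(mid[sp$functional_group == "C3_graminoid"]) + 1)
})

test_that("a pool without exotics yields zero exotic FP downstream", {
  sim <- simulate_dataset(synthetic_config(
    seed = 21, exotic_fraction = 0,
    n_sites = c(tallgrass = 1L), n_blocks = 1L))
  ex <- quietly(apply_exclusions(sim$cover, sim$catalog))
  fp <- fp_matrix(relativize(ex$included), sim$catalog,
                  subset_spec("provenance", "exotic"))
  expect_true(all(fp$fp == 0))
})

test_that("simulated plot totals overlap the canopy-overlap range", {
  sim <- simulate_dataset(synthetic_config(
    seed = 22, n_sites = c(tallgrass = 1L, mixedgrass = 1L,
                           shortgrass = 1L), n_blocks = 2L))
  totals <- dplyr::summarise(sim$cover, total = sum(cover_pct),
                             .by = c(site, block, plot))$total
  expect_true(all(totals <= 160 + 1e-6))
  expect_true(any(totals > 100))   # the over-100 relativization path
  expect_true(all(sim$cover$cover_pct > 0 & sim$cover$cover_pct <= 100))
})

test_that("empirical FP differences converge to the truth as noise vanishes", {
  cfg <- synthetic_config(
    seed = 23, noise_sd = 0,
    n_sites = c(tallgrass = 1L, mixedgrass = 1L, shortgrass = 1L),
    n_blocks = 1L, total_cover_range = c(80, 100))
  sim <- simulate_dataset(cfg)
  ex <- quietly(apply_exclusions(sim$cover, sim$catalog))
  fp <- fp_matrix(relativize(ex$included), sim$catalog)
  emp <- fp |>
    dplyr::mutate(grp = ifelse(trt_N, "N", "C")) |>
    dplyr::summarise(m = 100 * mean(fp), .by = c(ecoregion, month, grp)) |>
    tidyr::pivot_wider(names_from = grp, values_from = m) |>
    dplyr::mutate(diff = N - C) |>
    dplyr::arrange(ecoregion, month)
  truth <- dplyr::arrange(sim$truth, ecoregion, month)
  # covers are written to the nearest 1e-6 percent, so agreement is to
  # that rounding, not machine precision
  expect_lt(max(abs(emp$diff - truth$fp_diff_pct)), 1e-4)
})

test_that("the injected nitrogen effect raises early exotic FP in simulation", {
  diffs <- sapply(1:20, function(s) {
    sim <- simulate_dataset(synthetic_config(
      seed = 1000 + s, n_sites = c(tallgrass = 1L), n_blocks = 2L))
    ex <- quietly(apply_exclusions(sim$cover, sim$catalog))
    fp <- fp_matrix(relativize(ex$included), sim$catalog,
                    subset_spec("provenance", "exotic"))
    early <- fp[fp$month %in% 5:6, ]
    mean(early$fp[early$trt_N]) - mean(early$fp[!early$trt_N])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(noise_sd = -1))
  expect_error(synthetic_config(n_sites = c(alpine = 2L)))
  expect_error(synthetic_config(group_mix = c(forb = 0.5)))
  expect_error(synthetic_config(effect_N_late_C4 = 0))
  expect_error(synthetic_config(total_cover_range = c(100, 80)))
})
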