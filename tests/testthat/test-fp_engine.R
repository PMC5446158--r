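test_that("a June-August species adds its relative cover to exactly those months", {
  cat <- quietly(build_trait_catalog(tibble::tibble(
    taxon = c("Monarda fistulosa", "Solidago rigida"),
    flowering_months = list(6:8, 9L),
    provenance = "native", functional_group = "forb",
    lifeform = "herbaceous", source = "fixture")))
  comp <- tibble::tibble(
    site = "chb", ecoregion = "tallgrass", block = "b1", plot = "p61",
    trt_N = FALSE, trt_P = FALSE, trt_K = FALSE,
    taxon = cat$taxon, rel_cover = c(0.117, 0.883))
  expect_identical(monthly_fp(comp, cat, 6), 0.117)
  expect_identical(monthly_fp(comp, cat, 7), 0.117)
  expect_identical(monthly_fp(comp, cat, 8), 0.117)
  expect_identical(monthly_fp(comp, cat, 5), 0)
})

test_that("a full-cover species flowering May-Oct gives FP 1 in those months", {
  cat <- quietly(build_trait_catalog(tibble::tibble(
    taxon = "Solus omnium", flowering_months = list(5:10),
    provenance = "native", functional_group = "forb",
    lifeform = "herbaceous", source = "fixture")))
  comp <- tibble::tibble(site = "s", ecoregion = "tallgrass", block = "b",
                         plot = "p", trt_N = FALSE, trt_P = FALSE,
                         trt_K = FALSE, taxon = "Solus omnium",
                         rel_cover = 1)
  for (m in 1:12) {
    expect_equal(monthly_fp(comp, cat, m), as.numeric(m %in% 5:10))
  }
})

test_that("FP matches a brute-force species-by-month double loop", {
  set.seed(101)
  for (rep in 1:10) {
    cat <- random_catalog(10)
    comp <- random_composition(cat)
    fp <- fp_matrix(comp, cat)
    expect_equal(fp$fp, fp_brute_force(comp, cat), tolerance = 1e-12)
    for (m in c(1, 6, 10)) {
      expect_equal(monthly_fp(comp, cat, m), fp_brute_force(comp, cat)[m],
                   tolerance = 1e-12)
    }
    # subsets against the same oracle
    fp_ex <- fp_matrix(comp, cat, subset_spec("provenance", "exotic"))
    expect_equal(fp_ex$fp, fp_brute_force(comp, cat, "provenance", "exotic"),
                 tolerance = 1e-12)
    fp_c4 <- fp_matrix(comp, cat, subset_spec("functional_group",
                                              "C4_graminoid"))
    expect_equal(fp_c4$fp,
                 fp_brute_force(comp, cat, "functional_group",
                                "C4_graminoid"),
                 tolerance = 1e-12)
  }
})

test_that("provenance and functional-group FP partition the total", {
  set.seed(102)
  for (rep in 1:5) {
    cat <- random_catalog(15)   # all provenance known, all herbaceous
    comp <- dplyr::bind_rows(random_composition(cat, "p1"),
                             random_composition(cat, "p2"))
    total <- fp_matrix(comp, cat)$fp
    ex <- fp_matrix(comp, cat, subset_spec("provenance", "exotic"))$fp
    na <- fp_matrix(comp, cat, subset_spec("provenance", "native"))$fp
    expect_equal(total, ex + na, tolerance = 1e-9)
    fg_sum <- Reduce(`+`, lapply(
      c("C3_graminoid", "C4_graminoid", "forb", "legume"),
      function(g) fp_matrix(comp, cat,
                            subset_spec("functional_group", g))$fp))
    expect_equal(total, fg_sum, tolerance = 1e-9)
  }

  # with woody taxa present the herbaceous-group sum is a strict lower
  # bound on the total wherever a woody species is in flower
  cat_w <- random_catalog(10)
  cat_w$functional_group[1:2] <- "woody"
  comp_w <- random_composition(cat_w)
  total_w <- fp_matrix(comp_w, cat_w)$fp
  fg_w <- Reduce(`+`, lapply(
    c("C3_graminoid", "C4_graminoid", "forb", "legume"),
    function(g) fp_matrix(comp_w, cat_w,
                          subset_spec("functional_group", g))$fp))
  woody <- fp_matrix(comp_w, cat_w,
                     subset_spec("functional_group", "woody"))$fp
  expect_true(all(fg_w <= total_w + 1e-9))
  expect_equal(total_w, fg_w + woody, tolerance = 1e-9)
})

test_that("a graminoid-free community has identically zero graminoid FP", {
  cat <- random_catalog(8)
  cat$functional_group <- "forb"
  comp <- random_composition(cat)
  expect_identical(
    fp_matrix(comp, cat, subset_spec("functional_group", "C3_graminoid"))$fp,
    rep(0, 12))
})

test_that("FP is bounded, order-invariant, and monotone in flowering windows", {
  set.seed(103)
  cat <- random_catalog(12)
  comp <- random_composition(cat)
  fp <- fp_matrix(comp, cat)$fp
  expect_true(all(fp >= 0 & fp <= 1 + 1e-12))

  # permuting species rows changes nothing
  perm <- sample(nrow(comp))
  expect_equal(fp_matrix(comp[perm, ], cat)$fp, fp, tolerance = 1e-12)

  # enlarging one species' window never decreases any cell
  for (rep in 1:5) {
    cat2 <- cat
    i <- sample(nrow(cat2), 1)
    cat2$flowering_months[[i]] <-
      sort(unique(c(cat2$flowering_months[[i]], sample(1:12, 2))))
    expect_true(all(fp_matrix(comp, cat2)$fp >= fp - 1e-12))
  }

  # FP hits 1 exactly when every species in the plot flowers that month
  cat_all <- random_catalog(5)
  cat_all$flowering_months <- rep(list(7L), 5)
  comp_all <- random_composition(cat_all)
  expect_equal(fp_matrix(comp_all, cat_all)$fp[7], 1, tolerance = 1e-12)
})

test_that("a taxon without a trait record is an upstream error", {
  cat <- tiny_catalog()
  comp <- tibble::tibble(site = "s", ecoregion = "tallgrass", block = "b",
                         plot = "p", trt_N = FALSE, trt_P = FALSE,
                         trt_K = FALSE, taxon = "Ignotus maximus",
                         rel_cover = 1)
  expect_error(monthly_fp(comp, cat, 6), "Ignotus maximus")
  expect_error(fp_matrix(comp, cat), "Ignotus maximus")
})

test_that("subset specifications validate their labels", {
  expect_error(subset_spec("total", "exotic"), "no subset value")
  expect_error(subset_spec("provenance", "unknownish"), "native")
  expect_error(subset_spec("functional_group", "grass"), "C3_graminoid")
  expect_s3_class(subset_spec("provenance", "exotic"), "subset_spec")
})

test_that("group profiles average plots within nitrogen groups", {
  cat <- tiny_catalog()
  obs <- tiny_cover()
  fp <- fp_matrix(relativize(obs), cat)

  prof <- group_profiles(fp)
  expect_setequal(unique(prof$group), c("N_added", "N_free"))
  expect_equal(nrow(prof), 12L)   # 1 ecoregion x 6 months x 2 groups
  expect_true(all(prof$n == 4L))

  # spreadsheet oracle on one cell: tallgrass June, N-free plots
  nfree <- fp[fp$month == 6 & !fp$trt_N, ]
  cell <- prof[prof$month == 6 & prof$group == "N_free", ]
  expect_equal(cell$mean_fp_pct, 100 * mean(nfree$fp), tolerance = 1e-12)
  expect_equal(cell$se_fp_pct, 100 * sd(nfree$fp) / 2, tolerance = 1e-12)

  # two identical plots: SE zero; single plot: SE missing
  two <- fp[fp$plot %in% c("p1", "p3"), ]   # both nitrogen-free
  two$fp[two$plot == "p3"] <- two$fp[two$plot == "p1"]
  p2 <- group_profiles(two)
  expect_equal(p2$se_fp_pct[p2$n == 2L], rep(0, sum(p2$n == 2L)))
  one <- fp[fp$plot == "p1", ]
  p_one <- group_profiles(one)
  expect_true(all(is.na(p_one$se_fp_pct[p_one$n > 0])))
  # the absent nitrogen group is still reported, flagged with n = 0
  expect_true(all(p_one$n[p_one$group == "N_added"] == 0L))
})

test_that("group profiles keep requested months even when a group is empty", {
  cat <- tiny_catalog()
  fp <- fp_matrix(relativize(tiny_cover()), cat)
  prof <- group_profiles(fp[fp$trt_N, ], months = 5:7)
  expect_equal(nrow(prof), 6L)   # 3 months x 2 groups
  expect_true(all(prof$n[prof$group == "N_free"] == 0L))
  expect_true(all(is.na(prof$mean_fp_pct[prof$n == 0L])))
})

test_that("fp_long stacks subsets with percent-scale values", {
  cat <- tiny_catalog()
  fp <- fp_long(relativize(tiny_cover()), cat)
  expect_equal(nrow(fp), 8L * 12L * 7L)
  expect_equal(fp$fp_pct, 100 * fp$fp)
  expect_setequal(unique(fp$subset_value),
                  c("", "exotic", "native", "forb", "C3_graminoid",
                    "C4_graminoid", "legume"))
})
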