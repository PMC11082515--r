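test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- default_study_config()$shaded
  cfg$n_trees <- 3
  d1 <- generate_cohort(cfg, 7)
  d2 <- generate_cohort(cfg, 7)
  for (tab in c("trees", "discs", "vessels", "leaves", "stomata"))
    expect_identical(d1[[tab]], d2[[tab]])
  s1 <- generate_study(seed = 7)
  s2 <- generate_study(seed = 7)
  expect_identical(s1$discs, s2$discs)
  expect_false(identical(generate_cohort(cfg, 8)$discs, d1$discs))
})

test_that("structural invariants hold for every generated disc", {
  ds <- small_study(3)
  d <- ds$discs
  expect_true(all(d$hw_rings + d$sw_rings == d$cambial_age))
  expect_true(all(d$hw_present == (d$hw_rings >= 1)))
  expect_true(all(d$distance_from_top >= 0))
  expect_true(all(d$cambial_age >= 2))
  stem <- as.matrix(d[paste0("stem_r", 1:8)])
  hw <- as.matrix(d[paste0("hw_r", 1:8)])
  expect_true(all(hw <= stem + 1e-12))
  expect_true(all(hw[!d$hw_present, ] == 0))
  # leaf-area closure: a_L * n_leaves = A_L (unit-consistent)
  lv <- ds$leaves
  expect_equal(lv$mean_leaf_area * lv$n_leaves / 1e4, lv$total_leaf_area,
               tolerance = 1e-12)
  # vessel axes ordered and positive
  expect_true(all(ds$vessels$major >= ds$vessels$minor))
  expect_true(all(ds$vessels$minor > 0))
})

test_that("configuration invariants are enforced", {
  cfgs <- default_study_config()
  expect_silent(validate_cohort_config(cfgs$shaded))
  expect_silent(validate_cohort_config(cfgs$sun_exposed))
  bad <- cfgs$shaded; bad$diameter_growth_rate_mean <- -1
  expect_error(validate_cohort_config(bad), "non-positive")
  bad <- cfgs$shaded; bad$vessel_ellipticity <- 1.4
  expect_error(validate_cohort_config(bad), "ellipticity")
  bad <- cfgs$shaded; bad$n_trees <- 0
  expect_error(validate_cohort_config(bad), "n_trees")
  # trees too young to host two discs at the configured spacing
  expect_error(
    cohort_config(name = "tiny", n_trees = 2, age_range = c(3L, 4L),
                  diameter_growth_rate_mean = 0.3,
                  diameter_growth_rate_sd = 0.05, disc_interval = 2,
                  onset_logistic_a = -19.92, onset_logistic_b = 8,
                  onset_logistic_c = 1.8, hw_ring_rate = 1,
                  hw_area_power_a = 1e-6, hw_area_power_b = 4,
                  vessel_dh_mean = 100, vessel_dh_sd = 9,
                  vessel_density_mean = 18, vessel_density_sd = 3,
                  leaf_area_mean = 30, leaf_area_sd = 5,
                  leaf_area_rate = 0.5, stomatal_density_mean = 480,
                  stomatal_size_mean = 130),
    "too small")
  expect_error(generate_cohort(cfgs$shaded), "seed")
})

test_that("default study configuration encodes the cohort contrasts", {
  cfgs <- default_study_config()
  expect_equal(cfgs$shaded$diameter_growth_rate_mean, 0.30)
  expect_equal(cfgs$sun_exposed$diameter_growth_rate_mean, 1.02)
  expect_equal(cfgs$shaded$leaf_area_mean, 33.82)
  expect_equal(cfgs$sun_exposed$vessel_dh_mean, 123.55)
  expect_equal(cfgs$shaded$n_trees, 7)
  expect_equal(cfgs$sun_exposed$n_trees, 10)
  expect_equal(cfgs$shaded$disc_interval, 1)
  expect_equal(cfgs$sun_exposed$disc_interval, 2)
  # faster growers have the earlier age-onset truth
  thr <- function(cfg, gr) exp(-(cfg$onset_logistic_a +
                                   cfg$onset_logistic_c * log(gr)) /
                                 cfg$onset_logistic_b)
  expect_lt(thr(cfgs$sun_exposed, 1.02), thr(cfgs$shaded, 0.30))
  expect_equal(thr(cfgs$shaded, 0.30), 15.8, tolerance = 0.01)
  expect_equal(thr(cfgs$sun_exposed, 1.02), 12.0, tolerance = 0.01)
})

test_that("generated vessel traits match the configured cohort means", {
  cfg <- default_study_config()$sun_exposed   # D_H 123.55 +/- 8.81, 10 trees
  ds <- generate_cohort(cfg, 101)
  d <- disc_traits(ds$discs, ds$vessels)
  expect_lt(abs(mean(d$d_h, na.rm = TRUE) - 123.55), 2 * 8.81 / sqrt(10))
})

test_that("ring-conversion slope is recovered from generated discs", {
  cfg <- default_study_config()$sun_exposed   # truth 0.96 rings/yr
  cfg$n_trees <- 30
  cfg$vessels_per_disc <- 2
  ds <- generate_cohort(cfg, 202)
  d <- ds$discs[ds$discs$disc_type == "trunk" & ds$discs$hw_present, ]
  expect_gt(nrow(d), 200)
  slope <- unname(coef(lm(hw_rings ~ cambial_age, d))[2])
  expect_lt(abs(slope - 0.96), 0.05)
})

test_that("cohort-level trait means are calibrated at large n", {
  cfg <- default_study_config()$shaded
  cfg$n_trees <- 50
  cfg$vessels_per_disc <- 8
  ds <- generate_cohort(cfg, 404)
  d <- disc_traits(ds$discs, ds$vessels)
  trunk <- d[d$disc_type == "trunk", ]
  per_tree <- function(v) tapply(v, trunk$tree_id, mean, na.rm = TRUE)
  within_3se <- function(est, truth) {
    se <- sd(est) / sqrt(length(est))
    abs(mean(est) - truth) <= 3 * se
  }
  expect_true(within_3se(per_tree(trunk$gr), 0.30))
  expect_true(within_3se(per_tree(trunk$d_h), 101.33))
  expect_true(within_3se(per_tree(trunk$n_v), 18.06))
  a_l <- tapply(ds$leaves$mean_leaf_area, ds$leaves$tree_id, mean)
  expect_true(within_3se(a_l, 33.82))
})

test_that("datasets round-trip through the CSV schema", {
  ds <- small_study(9, n_shaded = 2, n_sun = 2, vessels = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trees.csv", "discs.csv", "vessels.csv", "leaves.csv", "stomata.csv",
      "truth.json")))))
  back <- read_dataset(dir)
  expect_equal(back$discs$cambial_age, ds$discs$cambial_age)
  expect_equal(back$discs$stem_r1, ds$discs$stem_r1, tolerance = 1e-10)
  expect_equal(back$vessels$major, ds$vessels$major, tolerance = 1e-10)
  expect_equal(back$truth$seed, ds$truth$seed)
})
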