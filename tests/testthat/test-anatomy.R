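test_that("hydraulic diameter matches direct arithmetic", {
  # circular case: one vessel of diameter d returns d exactly
  expect_identical(hydraulic_diameter(100, 100), 100)
  # two circular vessels, fourth-power mean
  expect_equal(hydraulic_diameter(c(50, 100)), ((50^4 + 100^4) / 2)^0.25,
               tolerance = 1e-12)
  # one ellipse 120 x 80
  expect_equal(hydraulic_diameter(120, 80),
               (2 * 120^3 * 80^3 / (120^2 + 80^2))^0.25, tolerance = 1e-12)
  expect_error(hydraulic_diameter(numeric(0)), "at least one")
  expect_error(hydraulic_diameter(c(100, -5)), "positive")
})

test_that("hydraulic diameter bounds and permutation invariance", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    a <- runif(n, 20, 200)
    b <- a * runif(n, 0.5, 1)
    dh <- hydraulic_diameter(a, b)
    term <- 2 * a^3 * b^3 / (a^2 + b^2)
    expect_gte(dh^4, min(term) - 1e-9)
    expect_lte(dh^4, max(term) + 1e-9)
    p <- sample(n)
    expect_equal(hydraulic_diameter(a[p], b[p]), dh, tolerance = 1e-12)
    # all-circular limit collapses to the fourth-power mean of diameters
    expect_equal(hydraulic_diameter(a, a), mean(a^4)^0.25,
                 tolerance = 1e-12)
  }
})

test_that("quadratic-mean radius is exact and dominates the arithmetic mean", {
  expect_identical(quadratic_mean_radius(rep(10, 8)), 10)
  expect_equal(quadratic_mean_radius(c(rep(6, 4), rep(8, 4))), sqrt(50),
               tolerance = 1e-12)
  expect_identical(quadratic_mean_radius(rep(0, 8)), 0)
  expect_error(quadratic_mean_radius(rep(5, 7)), "8 radii")
  expect_error(quadratic_mean_radius(c(rep(5, 7), -1)), "non-negative")
  set.seed(2)
  for (i in 1:20) {
    r <- runif(8, 0, 30)
    expect_gte(quadratic_mean_radius(r), mean(r))
  }
})

test_that("disc traits reproduce the area and vessel arithmetic", {
  mk_disc <- function(stem, hw, age, id = "d1") {
    out <- data.frame(tree_id = "t1", disc_id = id, cambial_age = age)
    out[paste0("stem_r", 1:8)] <- as.list(rep(stem, 8))
    out[paste0("hw_r", 1:8)] <- as.list(rep(hw, 8))
    out
  }
  d <- disc_traits(mk_disc(20, 10, 40))
  expect_equal(d$s_r, 20)
  expect_equal(d$sw_r, 10)
  expect_equal(d$csa, 400 * pi)
  expect_equal(d$hwa, 100 * pi)
  expect_equal(d$swa, 300 * pi)
  expect_equal(d$hw_proportion, 0.25)
  expect_equal(d$gr, 1)        # diameter 40 cm over 40 years
  expect_equal(disc_traits(mk_disc(15, 0, 30))$gr, 1)

  # vessel block: 5 circular vessels of lumen area 0.01 mm^2 at 15 mm^-2 on
  # a disc with 200 cm^2 of sapwood -> F_V = 15 %, TCVA = 30 cm^2
  d0 <- mk_disc(sqrt(200 / pi), 0, 25)
  dm <- 2 * sqrt(0.01 * 1e6 / pi)          # um diameter of a 0.01 mm^2 circle
  vs <- data.frame(tree_id = "t1", disc_id = "d1", vessel_id = 1:5,
                   major = dm, minor = dm, vessel_density = 15)
  dv <- disc_traits(d0, vs)
  expect_equal(dv$a_v, 0.01, tolerance = 1e-12)
  expect_equal(dv$f_v, 15, tolerance = 1e-12)
  expect_equal(dv$tcva, 30, tolerance = 1e-9)
  # branch discs without vessels carry missing, not zero, vessel traits
  d2 <- disc_traits(rbind(mk_disc(10, 2, 20), mk_disc(8, 1, 15, "d2")), vs)
  expect_true(is.na(d2$tcva[2]) && is.na(d2$d_h[2]))
  expect_false(is.na(d2$tcva[1]))
  # containment violation is an error
  expect_error(disc_traits(mk_disc(5, 6, 10)), "exceeds")
})

test_that("area closure holds on generated data", {
  ds <- small_study(11)
  d <- disc_traits(ds$discs, ds$vessels)
  expect_lt(max(abs(d$swa + d$hwa - d$csa) / d$csa), 1e-9)
  expect_true(all(d$hw_proportion >= 0 & d$hw_proportion < 1))
  ok <- !is.na(d$f_v)
  expect_true(all(d$f_v[ok] > 0 & d$f_v[ok] < 100))
  expect_true(all(d$tcva[ok] <= d$swa[ok]))
})

test_that("maximum stomatal conductance follows the anatomical formula", {
  # independent hand computation in SI units
  cons <- gmax_constants()
  D_s <- 300; S <- 100
  amax <- 0.12 * S * 1e-12
  pd <- sqrt(amax / pi)
  by_hand <- (2.49e-5 / 0.0245) * (D_s * 1e6) * amax /
    (pd + pi / 2 * sqrt(amax / pi))
  expect_equal(gmax(D_s, S, cons), by_hand, tolerance = 1e-12)
  # linear in stomatal density
  expect_equal(gmax(2 * D_s, S, cons), 2 * gmax(D_s, S, cons),
               tolerance = 1e-12)
  # strictly increasing in density
  g <- gmax(c(100, 200, 400), 120, cons)
  expect_true(all(diff(g) > 0))
  expect_error(gmax_constants(pore_area_fraction = 0), "pore_area_fraction")
  expect_error(gmax(-1, 100), "positive")
})

test_that("heartwood-proportion profiles order base to top with a trend sign", {
  prof_in <- data.frame(distance_from_top = c(2, 8, 5),
                        hw_proportion = c(0.1, 0.4, 0.25))
  p <- hw_proportion_profile(prof_in)
  expect_equal(p$distance_from_top, c(8, 5, 2))
  expect_identical(attr(p, "trend"), 1)
  flat <- data.frame(distance_from_top = c(2, 5, 8),
                     hw_proportion = rep(0.3, 3))
  expect_identical(attr(hw_proportion_profile(flat), "trend"), 0)
  expect_error(hw_proportion_profile(prof_in[1, ]), "at least 2")
  # generated sun-exposed tree: more heartwood at the base than at the top
  cfg <- default_study_config()$sun_exposed
  cfg$n_trees <- 3; cfg$vessels_per_disc <- 2
  ds <- generate_cohort(cfg, 21)
  d <- disc_traits(ds$discs, ds$vessels)
  d <- d[d$disc_type == "trunk", ]
  for (tid in unique(d$tree_id)) {
    p <- hw_proportion_profile(d[d$tree_id == tid, ])
    expect_gt(p$hw_proportion[1], p$hw_proportion[nrow(p)])
  }
})
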