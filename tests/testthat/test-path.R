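sim_path_data <- function(n, b_age = 0.6, b_hyd = 0.3, b_med = 0.7,
                          direct_age = 0, direct_hyd = 0) {
  Age <- rnorm(n); TCVA <- rnorm(n)
  v_d <- 1 - b_age^2 - b_hyd^2
  D <- b_age * Age + b_hyd * TCVA + rnorm(n, sd = sqrt(v_d))
  v_y <- 1 - (b_med^2 + direct_age^2 + direct_hyd^2)
  HWa <- b_med * D + direct_age * Age + direct_hyd * TCVA +
    rnorm(n, sd = sqrt(v_y))
  data.frame(Age = Age, TCVA = TCVA, D = D, HWa = HWa)
}

test_that("path coefficients equal explicit normal-equation solutions", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(12:50, 1)
    d <- sim_path_data(n)
    m <- fit_path(d, "HWa", "D", c("Age", "TCVA"))
    o <- path_oracle(d, "HWa", "D", c("Age", "TCVA"))
    expect_equal(unname(m$coefficients[1:2]), o$to_mediator,
                 tolerance = 1e-10)
    expect_equal(unname(m$coefficients[3]), o$mediator_to_outcome,
                 tolerance = 1e-10)
    expect_equal(unname(m$coefficients[4:5]), o$direct, tolerance = 1e-10)
  }
})

test_that("indirect effects are exact products and totals decompose", {
  set.seed(62)
  d <- sim_path_data(200)
  m <- fit_path(d, "HWa", "D", c("Age", "TCVA"))
  e <- m$effects
  pick <- function(src, kind) e$estimate[e$source == src & e$kind == kind]
  expect_equal(pick("Age", "indirect"),
               unname(m$coefficients[1] * m$coefficients[3]),
               tolerance = 1e-10)
  expect_equal(pick("Age", "total"),
               pick("Age", "direct") + pick("Age", "indirect"),
               tolerance = 1e-12)
  expect_equal(pick("TCVA", "total"),
               pick("TCVA", "direct") + pick("TCVA", "indirect"),
               tolerance = 1e-12)
})

test_that("standardization is idempotent and row order is irrelevant", {
  set.seed(63)
  d <- sim_path_data(80)
  z <- as.data.frame(scale(d))
  m1 <- fit_path(d, "HWa", "D", c("Age", "TCVA"))
  m2 <- fit_path(z, "HWa", "D", c("Age", "TCVA"))
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-12)
  expect_equal(m1$effects$estimate, m2$effects$estimate, tolerance = 1e-12)
  m3 <- fit_path(d[sample(nrow(d)), ], "HWa", "D", c("Age", "TCVA"))
  expect_equal(m1$effects$estimate, m3$effects$estimate, tolerance = 1e-12)
})

test_that("degenerate structures are caught", {
  set.seed(64)
  d <- sim_path_data(50)
  d$Y <- d$D                                   # outcome identical to mediator
  m <- fit_path(d, "Y", "D", c("Age", "TCVA"))
  e <- m$effects
  expect_equal(e$estimate[e$source == "D"], 1, tolerance = 1e-10)
  expect_equal(e$estimate[e$source == "Age" & e$kind == "direct"], 0,
               tolerance = 1e-10)
  d$Age2 <- d$Age                              # collinear exogenous pair
  expect_error(fit_path(d, "HWa", "D", c("Age", "Age2")), "collinear")
  d$const <- 1
  expect_error(fit_path(d, "HWa", "D", c("Age", "const")), "zero variance")
  expect_error(fit_path(d[1:5, ], "HWa", "D", c("Age", "TCVA")),
               "complete cases")
})

test_that("a seeded mediation simulation is recovered", {
  set.seed(65)
  d <- sim_path_data(2000)                     # indirect truths 0.42, 0.21
  m <- fit_path(d, "HWa", "D", c("Age", "TCVA"))
  e <- m$effects
  pick <- function(src, kind) e$estimate[e$source == src & e$kind == kind]
  expect_lt(abs(pick("Age", "direct")), 0.05)
  expect_lt(abs(pick("TCVA", "direct")), 0.05)
  expect_equal(pick("Age", "indirect"), 0.42, tolerance = 0.05 / 0.42)
  expect_equal(pick("TCVA", "indirect"), 0.21, tolerance = 0.05 / 0.21)
})

test_that("Wald contrasts are zero on self and detect unequal effects", {
  set.seed(66)
  d <- sim_path_data(2000)
  m <- fit_path(d, "HWa", "D", c("Age", "TCVA"))
  same <- wald_contrast(m, c("Age", "indirect"), c("Age", "indirect"))
  expect_identical(same$statistic, 0)
  expect_identical(same$p, 1)
  diff <- wald_contrast(m, c("Age", "indirect"), c("TCVA", "indirect"))
  expect_gt(diff$statistic, 0)
  expect_lt(diff$p, 0.01)                      # 0.42 vs 0.21 at n = 2000
  expect_error(wald_contrast(m, c("nope", "direct"), c("Age", "direct")),
               "unknown effect")
})
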