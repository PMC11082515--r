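test_that("the onset threshold is the closed-form inflection point", {
  f <- fake_occurrence_fit(a = -5, b = 2)
  th <- onset_threshold(f)
  expect_equal(th$point, exp(2.5), tolerance = 1e-12)
  expect_true(th$ci_low <= th$point && th$point <= th$ci_high)
  f2 <- fake_occurrence_fit(a = -9, b = 3.5, predictor = "age")
  expect_equal(onset_threshold(f2)$point, exp(9 / 3.5), tolerance = 1e-12)
  expect_identical(onset_threshold(f2)$scale, "years")
  # a slope indistinguishable from zero leaves the threshold undefined
  f3 <- fake_occurrence_fit(a = -1, b = 1e-14, se = 10)
  expect_error(onset_threshold(f3), "unidentifiable")
})

test_that("simulated occurrence data recover the logistic truth", {
  set.seed(31)
  d <- sim_occurrence(1000, a = -9, b = 3.5)
  f <- fit_occurrence(d, "age", "none")
  expect_true(f$converged)
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$a - (-9)), 3 * se[1])
  expect_lt(abs(f$b - 3.5), 3 * se[2])
  # the ML fit dominates the truth's likelihood on the same data
  mf <- f$model_frame
  ll_truth <- bern_loglik(mf$y, -9 + 3.5 * mf$logx)
  expect_gte(f$loglik, ll_truth)
  # fitted occurrence probability is monotone in the predictor when b > 0
  grid <- seq(min(mf$logx), max(mf$logx), length.out = 50)
  expect_true(all(diff(plogis(f$a + f$b * grid)) > 0))
})

test_that("thresholds are equivariant under predictor rescaling", {
  set.seed(32)
  d <- sim_occurrence(600, a = -9, b = 3.5)
  f1 <- fit_occurrence(d, "age", "none")
  d2 <- d; d2$cambial_age <- 3 * d2$cambial_age
  f2 <- fit_occurrence(d2, "age", "none")
  expect_equal(onset_threshold(f2)$point, 3 * onset_threshold(f1)$point,
               tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
})

test_that("degenerate outcomes and separation are flagged, not fitted", {
  d <- data.frame(hw_present = rep(1L, 20), diameter = 1:20)
  expect_error(fit_occurrence(d, "diameter", "none"), "one presence")
  d2 <- data.frame(hw_present = as.integer(1:40 > 20), diameter = 1:40)
  f <- fit_occurrence(d2, "diameter", "none")
  expect_false(f$converged)
  expect_error(onset_threshold(f), "non-converged")
  expect_error(fit_occurrence(
    data.frame(hw_present = c(0, 1), diameter = c(-1, 2)), "diameter"),
    "positive")
})

test_that("an uninformative covariate leaves the likelihood unchanged", {
  set.seed(33)
  d <- sim_occurrence(400, a = -9, b = 3.5)
  d$site <- 0                       # constant covariate carries no signal
  f0 <- fit_occurrence(d, "age", "none")
  f1 <- fit_occurrence(d, "age", "site")
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-6)
  expect_true(is.na(f1$c) || abs(f1$c) < 1e-6)
})

test_that("the covariate likelihood-ratio test is nested and exact at zero", {
  set.seed(34)
  d <- sim_occurrence(400, a = -9, b = 3.5, c_gr = 1.8)
  full <- fit_occurrence(d, "age", "gr")
  red <- fit_occurrence(d, "age", "none")
  out <- covariate_lrt(full, red)
  expect_gte(out$chi2, 0)
  expect_identical(out$df, 1L)
  expect_lt(out$p, 0.001)            # strong truth effect is detected
  same <- covariate_lrt(full, full)
  expect_identical(same$chi2, 0)
  expect_identical(same$p, 1)
  other <- fit_occurrence(d, "diameter", "none")
  expect_error(covariate_lrt(full, other), "nested")
})

test_that("delta and bootstrap threshold intervals agree", {
  set.seed(35)
  d <- sim_occurrence(1000, a = -9, b = 3.5)
  f <- fit_occurrence(d, "age", "none")
  del <- onset_threshold(f, ci = "delta")
  set.seed(36)
  boo <- onset_threshold(f, ci = "boot", n_boot = 800)
  expect_equal(boo$ci_low, del$ci_low, tolerance = 0.1)
  expect_equal(boo$ci_high, del$ci_high, tolerance = 0.1)
  expect_identical(boo$ci_method, "boot")
})

test_that("covariate thresholds are evaluated on the requested scale", {
  set.seed(37)
  d <- sim_occurrence(2000, a = -19.92, b = 8, c_gr = 1.8)
  f <- fit_occurrence(d, "age", "gr")
  expect_error(onset_threshold(f), "covariate_value")
  slow <- onset_threshold(f, covariate_value = 0.30)
  fast <- onset_threshold(f, covariate_value = 1.02)
  expect_lt(fast$point, slow$point)  # faster growers start earlier
  expect_equal(slow$point, 15.8, tolerance = 0.15)
})
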