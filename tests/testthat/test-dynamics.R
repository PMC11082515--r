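test_that("each family identifies its own noise-free data exactly", {
  x <- seq(1, 30, length.out = 40)
  truths <- list(
    linear = function(x) 2 + 0.8 * x,
    quadratic = function(x) 1 + 0.5 * x + 0.3 * x^2,
    power = function(x) 2 * x^1.5,
    asym_exp = function(x) 100 + (5 - 100) * exp(-0.1 * x))
  for (fam in names(truths)) {
    y <- truths[[fam]](x)
    f <- fit_family(x, y, fam)
    expect_true(f$converged)
    expect_lt(f$rss, 1e-10)
    sel <- select_model(lapply(names(truths), function(g)
      fit_family(x, y, g)))
    expect_identical(sel$chosen, fam)
  }
  f <- fit_family(x, 2 * x^1.5, "power")
  expect_equal(unname(f$params), c(2, 1.5), tolerance = 1e-6)
  f <- fit_family(x, 100 + (5 - 100) * exp(-0.1 * x), "asym_exp")
  expect_equal(predict(f, 0), 5, tolerance = 1e-6)      # intercept a1
  expect_equal(predict(f, 1e6), 100, tolerance = 1e-6)  # asymptote a0
  expect_equal(unname(f$params), c(100, 5, 0.1), tolerance = 1e-5)
  expect_gt(f$params[["a2"]], 0)
  expect_error(fit_family(c(-1, 2, 3, 4), c(1, 2, 3, 4), "power"),
               "positive")
})

test_that("selection prefers fewer parameters on ties and needs convergence", {
  mk <- function(family, rse, npar) {
    structure(list(family = family, params = c(a0 = 1, a1 = 1), rse = rse,
                   rss = rse^2, n = 10, npar = npar, converged = TRUE,
                   loglik = 0), class = "candidate_fit")
  }
  sel <- select_model(list(mk("quadratic", 1, 3L), mk("linear", 1, 2L)))
  expect_identical(sel$chosen, "linear")
  bad <- mk("power", 0.5, 2L); bad$converged <- FALSE
  sel2 <- select_model(list(bad, mk("linear", 1, 2L)))
  expect_identical(sel2$chosen, "linear")
  expect_error(select_model(list(bad)), "no candidate")
})

test_that("residual standard error is invariant to observation order", {
  set.seed(51)
  x <- runif(60, 1, 40); y <- 2 * x^0.8 + rnorm(60, sd = 0.5)
  f1 <- fit_family(x, y, "power")
  p <- sample(60)
  f2 <- fit_family(x[p], y[p], "power")
  expect_equal(f1$rse, f2$rse, tolerance = 1e-9)
  expect_equal(f1$params, f2$params, tolerance = 1e-7)
})

test_that("the quadratic truth wins model selection under noise", {
  set.seed(52)
  wins <- replicate(200, {
    x <- runif(50, 1, 10)
    y <- 1 + 0.5 * x + 0.3 * x^2 + rnorm(50, sd = 0.5)
    fams <- c("linear", "quadratic", "power", "asym_exp")
    sel <- select_model(lapply(fams, function(g) fit_family(x, y, g)))
    sel$chosen == "quadratic"
  })
  expect_gte(mean(wins), 0.9)
})

test_that("the group likelihood-ratio test nests correctly", {
  set.seed(53)
  x <- runif(50, 5, 50); y <- 2 * x^0.7 + rnorm(50, sd = 1)
  sh <- fit_family(c(x, x), c(y, y), "power")
  gl <- group_lrt(sh, list(fit_family(x, y, "power"),
                           fit_family(x, y, "power")))
  expect_lt(gl$chi2, 1e-6)
  expect_identical(gl$df, 2L)
  lin <- fit_family(x, y, "linear")
  expect_error(group_lrt(sh, list(lin, lin)), "same family")
  # slopes differing 2.6-fold are detected (multiplicative noise keeps the
  # response positive as heartwood areas are)
  hits <- replicate(20, {
    x1 <- runif(100, 5, 50); x2 <- runif(100, 5, 50)
    y1 <- 0.2 * x1^1.82 * exp(rnorm(100, sd = 0.2))
    y2 <- 0.2 * x2^0.7 * exp(rnorm(100, sd = 0.2))
    shf <- fit_family(c(x1, x2), c(y1, y2), "power")
    grp <- list(fit_family(x1, y1, "power"), fit_family(x2, y2, "power"))
    group_lrt(shf, grp)$p < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("first-ring age is the x-intercept with a working interval", {
  x <- seq(5, 60, by = 1)
  f <- fit_family(x, -15 + 1.0 * x, "linear")
  expect_equal(first_ring_age(f)$age, 15, tolerance = 1e-9)
  f2 <- fit_family(x, -8.64 + 0.96 * x, "linear")
  expect_equal(first_ring_age(f2)$age, 9.0, tolerance = 1e-9)
  # crossing-one convention shifts the age by 1/slope
  expect_equal(first_ring_age(f2, crossing = 1)$age, 9 + 1 / 0.96,
               tolerance = 1e-9)
  neg <- fit_family(x, 10 - 0.5 * x, "linear")
  expect_error(first_ring_age(neg), "positive")
  # delta and residual-bootstrap intervals agree
  set.seed(54)
  y <- -15 + 1.0 * x + rnorm(length(x), sd = 2)
  fb <- fit_family(x, y, "linear")
  del <- first_ring_age(fb)
  set.seed(55)
  boo <- first_ring_age(fb, ci = "boot", n_boot = 2000)
  expect_equal(boo$ci_low, del$ci_low, tolerance = 0.1)
  expect_equal(boo$ci_high, del$ci_high, tolerance = 0.1)
})
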