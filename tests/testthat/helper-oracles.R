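# Shared oracles and tiny simulators, independent of the implementation
# paths they cross-check.

# brute-force SMA slope: the SMA line minimises the sum of products of
# absolute vertical and horizontal residuals, sum (y - a - b x)^2 / |b|
# with a the centroid intercept; found by 1-D numerical minimisation
bf_sma_slope <- function(x, y) {
  loss <- function(b) {
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2) / abs(b)
  }
  s <- sign(cor(x, y)) * sd(y) / sd(x)
  stats::optimize(loss, interval = sort(c(s / 10, s * 10)),
                  tol = 1e-12)$minimum
}

# explicit normal-equation path solution from the raw covariance matrix
path_oracle <- function(d, outcome, mediator, exogenous) {
  R <- stats::cov2cor(stats::cov(d[c(mediator, exogenous, outcome)]))
  b1 <- solve(R[2:3, 2:3], R[2:3, 1])
  b2 <- solve(R[1:3, 1:3], R[1:3, 4])
  list(to_mediator = unname(b1), mediator_to_outcome = unname(b2[1]),
       direct = unname(b2[2:3]))
}

# Bernoulli log-likelihood of a logistic model at given coefficients
bern_loglik <- function(y, eta) sum(y * eta - log1p(exp(eta)))

# simulate heartwood occurrence from the logistic truth on log(age)
sim_occurrence <- function(n, a, b, c_gr = 0, meanlog = log(14),
                           sdlog = 0.6) {
  x <- exp(stats::rnorm(n, meanlog, sdlog))
  gr <- exp(stats::rnorm(n, -1, 0.4))
  eta <- a + b * log(x) + c_gr * log(gr)
  data.frame(hw_present = stats::rbinom(n, 1, stats::plogis(eta)),
             cambial_age = x, diameter = x, gr = gr)
}

# fabricate a converged occurrence fit with known coefficients
fake_occurrence_fit <- function(a, b, se = 1e-4,
                                predictor = "diameter") {
  V <- diag(c(se^2, se^2))
  dimnames(V) <- list(c("(Intercept)", "logx"), c("(Intercept)", "logx"))
  structure(list(a = a, b = b, c = NA_real_,
                 coefficients = c("(Intercept)" = a, logx = b),
                 vcov = V, loglik = 0, n = 100, converged = TRUE,
                 predictor = predictor, covariate = "none",
                 predictor_spec = if (predictor == "diameter") "logD"
                                  else "logAge",
                 model_frame = data.frame()),
            class = "occurrence_fit")
}

# a small two-cohort study scaled down for fast tests
small_study <- function(seed, n_shaded = 4, n_sun = 4, vessels = 5) {
  cfgs <- default_study_config()
  cfgs$shaded$n_trees <- n_shaded
  cfgs$sun_exposed$n_trees <- n_sun
  cfgs$shaded$vessels_per_disc <- vessels
  cfgs$sun_exposed$vessels_per_disc <- vessels
  generate_study(cfgs, seed)
}
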