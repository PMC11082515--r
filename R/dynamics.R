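# Candidate heartwood-dynamics models and selection by residual standard
# error.
#
# Families:
#   linear     y = a0 + a1*x
#   quadratic  y = a0 + a1*x + a2*x^2
#   power      y = a0 * x^a1
#   asym_exp   y = a0 + (a1 - a0) * exp(-a2*x)   (a0 asymptote, a1 value at
#              x = 0, a2 > 0 relative rate; a2 is fitted on the log scale)
#
# Nonlinear families use deterministic multistart Levenberg-Marquardt least
# squares (starting values from data-driven heuristics, e.g. the power
# exponent from an ln-ln ordinary regression), so fits are reproducible
# without any random seed.

.family_npar <- c(linear = 2L, quadratic = 3L, power = 2L, asym_exp = 3L)
.family_order <- c("linear", "power", "quadratic", "asym_exp")

.gauss_loglik <- function(rss, n) -n / 2 * (base::log(2 * pi * rss / n) + 1)

.mk_fit <- function(family, params, ses, rss, n, converged, fitted, x, y) {
  p <- .family_npar[[family]]
  structure(list(family = family, params = params, param_ses = ses,
                 rss = rss, rse = sqrt(rss / max(n - p, 1)), n = n,
                 npar = p, converged = converged,
                 loglik = .gauss_loglik(max(rss, 1e-300), n),
                 fitted = fitted, x = x, y = y),
            class = "candidate_fit")
}

.fit_nls_multistart <- function(formula, data, starts, lower = NULL) {
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                     maxiter = 500)
  for (st in starts) {
    f <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(formula, data = data, start = st,
                                         control = ctrl)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss))
        best <- list(fit = f, rss = rss)
    }
  }
  best
}

#' Fit one candidate heartwood-dynamics model family
#'
#' Least-squares fit of one of the four candidate families relating a
#' heartwood quantity (area, proportion or ring count) to stem diameter or
#' cambial age. The residual standard error is
#' \eqn{\sqrt{RSS/(n - p)}}; the Gaussian log-likelihood is stored for
#' nested likelihood-ratio testing.
#'
#' @param x,y numeric vectors; for \code{family = "power"} both must be
#'   strictly positive.
#' @param family one of \code{"linear"}, \code{"quadratic"}, \code{"power"},
#'   \code{"asym_exp"}.
#' @return object of class \code{candidate_fit} with \code{params} (named
#'   \code{a0, a1[, a2]}), \code{param_ses}, \code{rse}, \code{rss},
#'   \code{loglik}, \code{n}, \code{converged} and the data.
#' @export
fit_family <- function(x, y,
                       family = c("linear", "quadratic", "power",
                                  "asym_exp")) {
  family <- match.arg(family)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < .family_npar[[family]] + 1L)
    stop("need at least ", .family_npar[[family]] + 1L,
         " observations for family '", family, "'")

  if (family %in% c("linear", "quadratic")) {
    fit <- if (family == "linear") stats::lm(y ~ x)
           else stats::lm(y ~ x + I(x^2))
    cf <- unname(stats::coef(fit))
    ses <- unname(sqrt(diag(stats::vcov(fit))))
    params <- stats::setNames(cf, paste0("a", seq_along(cf) - 1))
    ses <- stats::setNames(ses, names(params))
    out <- .mk_fit(family, params, ses, sum(stats::resid(fit)^2), n,
                   TRUE, unname(stats::fitted(fit)), x, y)
    out$vcov <- unname(stats::vcov(fit))
    dimnames(out$vcov) <- list(names(params), names(params))
    return(out)
  }

  dat <- data.frame(x = x, y = y)
  if (family == "power") {
    if (any(x <= 0) || any(y <= 0))
      stop("power family needs strictly positive x and y")
    ll <- stats::lm(base::log(y) ~ base::log(x))
    b0 <- unname(stats::coef(ll)[2]); a0 <- exp(unname(stats::coef(ll)[1]))
    starts <- list(list(a = a0, b = b0),
                   list(a = a0 * 0.5, b = b0),
                   list(a = a0 * 2, b = b0),
                   list(a = a0, b = b0 * 0.8),
                   list(a = a0, b = b0 * 1.25))
    best <- .fit_nls_multistart(y ~ a * x^b, dat, starts)
    if (is.null(best))
      return(.mk_fit("power", c(a0 = NA_real_, a1 = NA_real_),
                     c(a0 = NA_real_, a1 = NA_real_), Inf, n, FALSE,
                     rep(NA_real_, n), x, y))
    cf <- stats::coef(best$fit)
    V <- stats::vcov(best$fit)
    params <- c(a0 = unname(cf["a"]), a1 = unname(cf["b"]))
    ses <- c(a0 = sqrt(V["a", "a"]), a1 = sqrt(V["b", "b"]))
    out <- .mk_fit("power", params, ses, best$rss, n, TRUE,
                   unname(stats::fitted(best$fit)), x, y)
    out$vcov <- matrix(V, 2, 2, dimnames = list(names(params), names(params)))
    return(out)
  }

  # asym_exp, rate parametrised as exp(la2) for positivity
  ylo <- mean(y[x <= stats::quantile(x, 0.2)])
  yhi <- mean(y[x >= stats::quantile(x, 0.8)])
  rng <- diff(range(x))
  la2_0 <- base::log(2 / max(rng, 1e-6))
  starts <- list(
    list(a0 = yhi + 0.1 * (yhi - ylo), a1 = ylo - 0.05 * (yhi - ylo),
         la2 = la2_0),
    list(a0 = yhi + 0.1 * (yhi - ylo), a1 = ylo - 0.05 * (yhi - ylo),
         la2 = la2_0 + base::log(3)),
    list(a0 = yhi + 0.1 * (yhi - ylo), a1 = ylo - 0.05 * (yhi - ylo),
         la2 = la2_0 - base::log(3)),
    list(a0 = yhi + 0.3 * abs(yhi - ylo) + 1e-3, a1 = ylo, la2 = la2_0),
    list(a0 = max(y) + 0.05 * abs(max(y)) + 1e-3, a1 = min(y),
         la2 = la2_0 + base::log(10)))
  best <- .fit_nls_multistart(y ~ a0 + (a1 - a0) * exp(-exp(la2) * x),
                              dat, starts)
  if (is.null(best))
    return(.mk_fit("asym_exp",
                   c(a0 = NA_real_, a1 = NA_real_, a2 = NA_real_),
                   c(a0 = NA_real_, a1 = NA_real_, a2 = NA_real_),
                   Inf, n, FALSE, rep(NA_real_, n), x, y))
  cf <- stats::coef(best$fit)
  V <- stats::vcov(best$fit)
  a2 <- exp(unname(cf["la2"]))
  params <- c(a0 = unname(cf["a0"]), a1 = unname(cf["a1"]), a2 = a2)
  ses <- c(a0 = sqrt(V["a0", "a0"]), a1 = sqrt(V["a1", "a1"]),
           a2 = a2 * sqrt(V["la2", "la2"]))   # delta method on exp(la2)
  out <- .mk_fit("asym_exp", params, ses, best$rss, n, TRUE,
                 unname(stats::fitted(best$fit)), x, y)
  out$vcov <- V
  out
}

#' @export
print.candidate_fit <- function(x, ...) {
  cat(sprintf("Candidate dynamics fit: %s (n = %d)%s\n", x$family, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(rbind(estimate = x$params, se = x$param_ses), 5))
  cat(sprintf("  RSE = %.5g, logLik = %.3f\n", x$rse, x$loglik))
  invisible(x)
}

#' Evaluate a fitted candidate model at new x
#'
#' @param object a \code{candidate_fit}.
#' @param newdata optional numeric vector of x values (defaults to the data).
#' @param ... unused.
#' @export
predict.candidate_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  p <- object$params
  switch(object$family,
         linear = p[["a0"]] + p[["a1"]] * x,
         quadratic = p[["a0"]] + p[["a1"]] * x + p[["a2"]] * x^2,
         power = p[["a0"]] * x^p[["a1"]],
         asym_exp = p[["a0"]] + (p[["a1"]] - p[["a0"]]) * exp(-p[["a2"]] * x))
}

#' Select the best candidate model by residual standard error
#'
#' Picks the converged fit with the lowest RSE. Ties (within a relative
#' tolerance) are broken in favour of fewer parameters, then by the fixed
#' family order linear, power, quadratic, asym_exp.
#'
#' @param fits list of [fit_family()] objects on the same data.
#' @param tie_tol relative RSE tolerance treated as a tie.
#' @return object of class \code{model_selection}: \code{fits},
#'   \code{chosen} (family name), \code{best} (the chosen fit),
#'   \code{criterion = "rse"}.
#' @export
select_model <- function(fits, tie_tol = 1e-9) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "candidate_fit")))
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no candidate fit converged")
  rses <- vapply(conv, `[[`, 0, "rse")
  best_rse <- min(rses)
  # relative tie band plus a tiny absolute floor so that exact fits
  # (rse ~ machine zero) tie regardless of their residual rounding
  tied <- conv[rses <= best_rse * (1 + tie_tol) + 1e-12]
  np <- vapply(tied, `[[`, 0L, "npar")
  tied <- tied[np == min(np)]
  fams <- vapply(tied, `[[`, "", "family")
  best <- tied[[which.min(match(fams, .family_order))]]
  structure(list(fits = fits, chosen = best$family, best = best,
                 criterion = "rse"),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  tab <- data.frame(
    family = vapply(x$fits, `[[`, "", "family"),
    rse = vapply(x$fits, `[[`, 0, "rse"),
    converged = vapply(x$fits, `[[`, TRUE, "converged"))
  tab$chosen <- ifelse(tab$family == x$chosen, "*", "")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test of group-specific versus shared dynamics
#'
#' Gaussian likelihood-ratio test comparing one fit shared across groups
#' against separate fits per group (same family, same records):
#' \eqn{\chi^2 = n \ln(RSS_{shared}/RSS_{group})}, df = extra parameters.
#'
#' @param shared_fit a [fit_family()] on all records pooled.
#' @param group_fits list of [fit_family()] of the same family, one per
#'   group, jointly covering the same records.
#' @return list \code{(chi2, df, p)}.
#' @export
group_lrt <- function(shared_fit, group_fits) {
  stopifnot(inherits(shared_fit, "candidate_fit"))
  if (inherits(group_fits, "candidate_fit")) group_fits <- list(group_fits)
  fams <- vapply(group_fits, `[[`, "", "family")
  if (!all(fams == shared_fit$family))
    stop("group fits must use the same family as the shared fit")
  n_group <- sum(vapply(group_fits, `[[`, 0, "n"))
  if (n_group != shared_fit$n)
    stop("group fits do not cover the same records as the shared fit")
  rss_g <- sum(vapply(group_fits, `[[`, 0, "rss"))
  df <- sum(vapply(group_fits, `[[`, 0L, "npar")) - shared_fit$npar
  if (df < 1) stop("group model does not nest the shared model")
  chi2 <- max(0, shared_fit$n * base::log(shared_fit$rss / rss_g))
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Age at which the first ring is converted to heartwood
#'
#' From a linear fit of the number of heartwood rings on cambial age, the
#' age at which the fitted line crosses \code{crossing} rings (0 by default;
#' 1 is the "first complete ring" convention):
#' \eqn{age = (crossing - a_0)/a_1}. The CI is by the delta method on the
#' coefficient covariance, or by residual bootstrap refitting.
#'
#' @param fit a linear [fit_family()] with positive slope.
#' @param crossing ring count defining "first ring" (0 or 1).
#' @param alpha CI level is \code{1 - alpha}.
#' @param ci \code{"delta"} or \code{"boot"}.
#' @param n_boot bootstrap draws when \code{ci = "boot"}.
#' @return list \code{(age, ci_low, ci_high, crossing, ci_method)}.
#' @export
first_ring_age <- function(fit, crossing = 0, alpha = 0.05,
                           ci = c("delta", "boot"), n_boot = 2000) {
  ci <- match.arg(ci)
  stopifnot(inherits(fit, "candidate_fit"))
  if (fit$family != "linear") stop("first-ring age needs a linear fit")
  a0 <- fit$params[["a0"]]; a1 <- fit$params[["a1"]]
  if (a1 <= 0) stop("slope must be positive to define a first-ring age")
  age <- (crossing - a0) / a1
  if (ci == "delta") {
    grad <- c(-1 / a1, -(crossing - a0) / a1^2)
    se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
    zq <- stats::qnorm(1 - alpha / 2)
    lo <- age - zq * se; hi <- age + zq * se
  } else {
    res <- fit$y - fit$fitted
    ages <- vapply(seq_len(n_boot), function(i) {
      yb <- fit$fitted + sample(res, replace = TRUE)
      cf <- stats::coef(stats::lm(yb ~ fit$x))
      (crossing - cf[1]) / cf[2]
    }, 0)
    qs <- stats::quantile(ages, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(age = age, ci_low = lo, ci_high = hi, crossing = crossing,
       ci_method = ci)
}
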