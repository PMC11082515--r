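# Heartwood-onset estimation: logistic occurrence models on log size / log
# age, inflection-point thresholds, and nested covariate tests.
#
# The occurrence model is P = logistic(a + b*ln(x) [+ c*z]) with x the stem
# diameter (cm) or cambial age (years) and z an optional covariate: site
# (shaded = 0, sun-exposed = 1) or ln growth rate (cm/yr). The size or age
# threshold of heartwood onset is the inflection point of the fitted curve,
# x_0.5 = exp(-(a + c*z)/b).

#' Fit a logistic heartwood-occurrence model
#'
#' Maximum-likelihood logistic regression of heartwood presence/absence on
#' the natural log of stem diameter or cambial age, optionally with a site
#' indicator or log growth rate as covariate. Fitting is by binomial IRLS
#' (\code{stats::glm}); complete separation is flagged as a non-converged
#' fit rather than silently reported.
#'
#' @param data data.frame with columns \code{hw_present} (logical or 0/1)
#'   and, as needed, \code{diameter} (cm) or \code{cambial_age} (years),
#'   \code{site} (0 = shaded, 1 = sun-exposed) or \code{gr} (cm/yr).
#' @param predictor \code{"diameter"} or \code{"age"}.
#' @param covariate \code{"none"}, \code{"site"} or \code{"gr"} (entered as
#'   \code{log(gr)}).
#' @return object of class \code{occurrence_fit}: coefficients \code{a}
#'   (intercept), \code{b} (slope on the log predictor), \code{c}
#'   (covariate, or NA), \code{vcov}, \code{loglik}, \code{n},
#'   \code{converged}, \code{predictor_spec}, and the model frame.
#' @export
fit_occurrence <- function(data,
                           predictor = c("diameter", "age"),
                           covariate = c("none", "site", "gr")) {
  predictor <- match.arg(predictor)
  covariate <- match.arg(covariate)
  pcol <- switch(predictor, diameter = "diameter", age = "cambial_age")
  if (!pcol %in% names(data)) stop("missing column '", pcol, "'")
  if (!"hw_present" %in% names(data)) stop("missing column 'hw_present'")
  y <- as.integer(data$hw_present)
  x <- data[[pcol]]
  if (any(x <= 0, na.rm = TRUE)) stop("'", pcol, "' must be strictly positive")
  z <- switch(covariate,
              none = NULL,
              site = {
                if (!"site" %in% names(data)) stop("missing column 'site'")
                as.numeric(data$site)
              },
              gr = {
                if (!"gr" %in% names(data)) stop("missing column 'gr'")
                if (any(data$gr <= 0, na.rm = TRUE))
                  stop("'gr' must be strictly positive")
                base::log(data$gr)
              })
  mf <- data.frame(y = y, logx = base::log(x))
  if (!is.null(z)) mf$z <- z
  mf <- mf[stats::complete.cases(mf), ]
  if (sum(mf$y == 1) < 1 || sum(mf$y == 0) < 1)
    stop("need at least one presence and one absence of heartwood")

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = mf, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  # diverging coefficients indicate (quasi-)separation
  converged <- fit$converged && !(sep_warn && max(abs(cf)) > 50)
  spec <- paste0(if (predictor == "diameter") "logD" else "logAge",
                 switch(covariate, none = "", site = "+site", gr = "+logGR"))
  structure(list(a = unname(cf["(Intercept)"]),
                 b = unname(cf["logx"]),
                 c = if (covariate == "none") NA_real_ else unname(cf["z"]),
                 coefficients = cf,
                 vcov = stats::vcov(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 n = nrow(mf),
                 converged = converged,
                 predictor = predictor, covariate = covariate,
                 predictor_spec = spec,
                 model_frame = mf),
            class = "occurrence_fit")
}

#' @export
print.occurrence_fit <- function(x, ...) {
  cat("Logistic heartwood-occurrence model:", x$predictor_spec, "\n")
  cat(sprintf("  a = %.4f, b = %.4f%s; logLik = %.3f, n = %d%s\n",
              x$a, x$b,
              if (!is.na(x$c)) sprintf(", c = %.4f", x$c) else "",
              x$loglik, x$n,
              if (x$converged) "" else "  [NOT CONVERGED / separation]"))
  invisible(x)
}

#' Onset threshold as the inflection point of the occurrence curve
#'
#' The diameter or age at which the fitted probability of heartwood presence
#' crosses 0.5: \eqn{x_{0.5} = \exp(-(a + c z)/b)}. The confidence interval
#' is computed by the delta method on the log-scale threshold
#' \eqn{-(a + cz)/b} (default) or by parametric bootstrap (responses
#' re-simulated from the fitted probabilities and the model refitted).
#'
#' @param fit a converged [fit_occurrence()] model.
#' @param covariate_value value of the covariate at which to evaluate the
#'   threshold (site code, or growth rate in cm/yr for the \code{gr} model —
#'   logged internally). Required when the fit has a covariate.
#' @param alpha the CI is at level \code{1 - alpha}.
#' @param ci \code{"delta"} or \code{"boot"}.
#' @param n_boot bootstrap replicates when \code{ci = "boot"}.
#' @return object of class \code{onset_threshold} with \code{point},
#'   \code{ci_low}, \code{ci_high}, \code{scale} ("cm" or "years"),
#'   \code{covariate_value} and \code{ci_method}.
#' @export
onset_threshold <- function(fit, covariate_value = NULL, alpha = 0.05,
                            ci = c("delta", "boot"), n_boot = 1000) {
  ci <- match.arg(ci)
  stopifnot(inherits(fit, "occurrence_fit"))
  if (!fit$converged) stop("threshold from a non-converged fit is undefined")
  has_cov <- fit$covariate != "none"
  if (has_cov && is.null(covariate_value))
    stop("this model has a covariate: supply 'covariate_value'")
  z <- if (!has_cov) 0 else {
    if (fit$covariate == "gr") {
      if (covariate_value <= 0) stop("growth rate must be positive")
      base::log(covariate_value)
    } else as.numeric(covariate_value)
  }
  a <- fit$a; b <- fit$b; cc <- if (has_cov) fit$c else 0
  se_b <- sqrt(fit$vcov["logx", "logx"])
  if (abs(b) < 1e-8 * se_b || b == 0)
    stop("slope b is indistinguishable from zero: threshold unidentifiable")
  g <- -(a + cc * z) / b   # log-scale threshold

  if (ci == "delta") {
    grad <- c(-1 / b, (a + cc * z) / b^2)
    V <- fit$vcov[c("(Intercept)", "logx"), c("(Intercept)", "logx")]
    if (has_cov) {
      grad <- c(grad, -z / b)
      V <- fit$vcov
    }
    se_g <- sqrt(drop(t(grad) %*% V %*% grad))
    zq <- stats::qnorm(1 - alpha / 2)
    lo <- exp(g - zq * se_g); hi <- exp(g + zq * se_g)
  } else {
    mf <- fit$model_frame
    eta <- as.matrix(cbind(1, mf[, setdiff(names(mf), "y"), drop = FALSE])) %*%
      fit$coefficients
    p_hat <- stats::plogis(drop(eta))
    gs <- vapply(seq_len(n_boot), function(i) {
      mf$y <- stats::rbinom(nrow(mf), 1, p_hat)
      bf <- suppressWarnings(
        stats::glm(y ~ ., data = mf, family = stats::binomial()))
      cf <- stats::coef(bf)
      cz <- if (has_cov) cf["z"] * z else 0
      -(cf["(Intercept)"] + cz) / cf["logx"]
    }, 0)
    qs <- stats::quantile(gs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- exp(qs[1]); hi <- exp(qs[2])
  }
  structure(list(point = exp(g), ci_low = lo, ci_high = hi,
                 scale = if (fit$predictor == "diameter") "cm" else "years",
                 covariate_value = if (has_cov) covariate_value else NA_real_,
                 alpha = alpha, ci_method = ci),
            class = "onset_threshold")
}

#' @export
print.onset_threshold <- function(x, ...) {
  cat(sprintf("Heartwood-onset threshold: %.2f %s [%.2f, %.2f] (%s CI%s)\n",
              x$point, x$scale, x$ci_low, x$ci_high, x$ci_method,
              if (!is.na(x$covariate_value))
                sprintf(", covariate = %.3g", x$covariate_value) else ""))
  invisible(x)
}

#' Likelihood-ratio test for a covariate in the occurrence model
#'
#' Compares two nested occurrence fits on the same records:
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})}, df = difference in
#' coefficient count.
#'
#' @param full,reduced [fit_occurrence()] objects; \code{reduced} must use a
#'   subset of \code{full}'s predictors and the same records.
#' @return list \code{(chi2, df, p)}.
#' @export
covariate_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "occurrence_fit"),
            inherits(reduced, "occurrence_fit"))
  if (full$predictor != reduced$predictor)
    stop("models use different log predictors: not nested")
  full_terms <- c("logx", if (full$covariate != "none") "z")
  red_terms <- c("logx", if (reduced$covariate != "none") "z")
  if (!all(red_terms %in% full_terms) ||
      (reduced$covariate != "none" && reduced$covariate != full$covariate))
    stop("'reduced' is not nested in 'full'")
  if (full$n != reduced$n)
    stop("models were fitted on different numbers of records")
  df <- length(full$coefficients) - length(reduced$coefficients)
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}
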