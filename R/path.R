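# Recursive path analysis: standardized direct and indirect effects of age
# and a hydraulic variable on a heartwood/sapwood quantity, with stem
# diameter as the mediator.
#
# The system is recursive and Gaussian:
#   mediator ~ exo1 + exo2
#   outcome  ~ mediator + exo1 + exo2
# All variables are z-scored first, so equation-wise ordinary least squares
# is the maximum-likelihood estimator and the coefficients are standardized
# path coefficients. Standard errors of the (direct, indirect, total)
# effects use the delta method over the sampling distribution of the raw
# covariance matrix, which propagates the uncertainty of the
# standardization itself (a per-equation OLS covariance on z-scores does
# not, and is anticonservative for Wald contrasts of strong effects).

.zscore <- function(v) (v - mean(v)) / stats::sd(v)

# all seven standardized effects as a smooth function of the raw covariance
# matrix S (variable order: mediator, exo1, exo2, outcome): the path
# coefficients are the normal-equation solutions on the correlation matrix
.effects_from_cov <- function(S) {
  R <- stats::cov2cor(S)
  b1 <- solve(R[2:3, 2:3], R[2:3, 1])        # exogenous -> mediator
  b2 <- solve(R[1:3, 1:3], R[1:3, 4])        # (mediator, exogenous) -> outcome
  m <- b2[1]; dir <- b2[2:3]; ind <- b1 * m
  c(dir1 = dir[1], ind1 = ind[1], tot1 = dir[1] + ind[1],
    dir2 = dir[2], ind2 = ind[2], tot2 = dir[2] + ind[2],
    med = m)
}

# delta-method covariance of the seven effects over the sampling
# distribution of S (normal theory: cov(s_ij, s_kl) =
# (S_ik S_jl + S_il S_jk)/n), so the uncertainty of the standardization
# itself is propagated -- the naive per-equation OLS covariance of
# coefficients on z-scores ignores it and is anticonservative for
# contrasts of strong effects
.moment_vcov_effects <- function(S, n) {
  idx <- which(lower.tri(S, diag = TRUE), arr.ind = TRUE)
  K <- nrow(idx)
  J <- matrix(0, 7L, K)
  for (k in seq_len(K)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    h <- 1e-6 * sqrt(S[i, i] * S[j, j])
    Sp <- S; Sp[i, j] <- Sp[i, j] + h; Sp[j, i] <- Sp[i, j]
    Sm <- S; Sm[i, j] <- Sm[i, j] - h; Sm[j, i] <- Sm[i, j]
    J[, k] <- (.effects_from_cov(Sp) - .effects_from_cov(Sm)) / (2 * h)
  }
  Om <- matrix(0, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      i <- idx[a, 1]; j <- idx[a, 2]; k <- idx[b, 1]; l <- idx[b, 2]
      Om[a, b] <- (S[i, k] * S[j, l] + S[i, l] * S[j, k]) / n
    }
  }
  J %*% Om %*% t(J)
}

#' Fit a recursive path model (mediation through stem diameter)
#'
#' Estimates the standardized direct, indirect (through the mediator) and
#' total effects of two exogenous variables (typically cambial age and a
#' hydraulic variable such as TCVA or total leaf area) on an outcome
#' (heartwood or sapwood area). Identity enforced by construction:
#' indirect = (source -> mediator) x (mediator -> outcome), and
#' total = direct + indirect.
#'
#' @param data data.frame holding all four variables.
#' @param outcome,mediator character column names.
#' @param exogenous character vector of two column names.
#' @param condition_max collinearity guard: error if the condition number of
#'   the predictor correlation matrix exceeds this.
#' @return object of class \code{path_model}: \code{coefficients} (the five
#'   standardized paths), \code{vcov} (their block-diagonal per-equation
#'   covariance), \code{effects} (data.frame with source, kind, estimate,
#'   se, z, p), \code{effects_vcov} (moment-delta covariance of the seven
#'   effects), \code{n}, and \code{exo_cor} (correlation between the
#'   exogenous variables).
#' @export
fit_path <- function(data, outcome, mediator, exogenous,
                     condition_max = 1e8) {
  stopifnot(is.data.frame(data), length(exogenous) == 2L)
  vars <- c(mediator, exogenous, outcome)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[vars]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 10L) stop("need at least 10 complete cases")
  sds <- vapply(d, stats::sd, 0)
  if (any(sds == 0))
    stop("zero variance in: ", paste(vars[sds == 0], collapse = ", "))
  z <- as.data.frame(lapply(d, .zscore))

  R <- stats::cor(z[c(mediator, exogenous)])
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) / max(min(ev), 1e-300) > condition_max) {
    off <- abs(R); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("collinear predictors: ", rownames(R)[worst[1]], " and ",
         colnames(R)[worst[2]])
  }

  f1 <- stats::as.formula(paste0("`", mediator, "` ~ `", exogenous[1],
                                 "` + `", exogenous[2], "`"))
  f2 <- stats::as.formula(paste0("`", outcome, "` ~ `", mediator, "` + `",
                                 exogenous[1], "` + `", exogenous[2], "`"))
  m1 <- stats::lm(f1, data = z)
  m2 <- stats::lm(f2, data = z)
  th <- c(stats::coef(m1)[-1], stats::coef(m2)[-1])
  names(th) <- c(paste0(exogenous, "->", mediator),
                 paste0(mediator, "->", outcome),
                 paste0(exogenous, "->", outcome))
  V <- matrix(0, 5, 5, dimnames = list(names(th), names(th)))
  V[1:2, 1:2] <- stats::vcov(m1)[-1, -1]
  V[3:5, 3:5] <- stats::vcov(m2)[-1, -1]

  S <- stats::cov(d[c(mediator, exogenous, outcome)])
  f0 <- .effects_from_cov(S)
  V_eff <- .moment_vcov_effects(S, nrow(d))
  dimnames(V_eff) <- list(names(f0), names(f0))
  key <- c(dir1 = 1, ind1 = 1, tot1 = 1, dir2 = 2, ind2 = 2, tot2 = 2,
           med = 0)
  kind <- c("direct", "indirect", "total", "direct", "indirect", "total",
            "direct")
  eff <- data.frame(
    source = c(exogenous[1], exogenous[1], exogenous[1],
               exogenous[2], exogenous[2], exogenous[2], mediator),
    kind = kind, estimate = unname(f0), se = sqrt(pmax(diag(V_eff), 0)),
    stringsAsFactors = FALSE)
  eff$z <- eff$estimate / eff$se
  eff$p <- 2 * stats::pnorm(-abs(eff$z))
  rownames(eff) <- NULL

  structure(list(coefficients = th, vcov = V, effects = eff,
                 effects_vcov = V_eff, n = nrow(d),
                 outcome = outcome, mediator = mediator,
                 exogenous = exogenous,
                 exo_cor = stats::cor(z[[exogenous[1]]], z[[exogenous[2]]]),
                 equations = list(mediator = m1, outcome = m2)),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Recursive path model: %s ~ %s + (%s), n = %d\n",
              x$outcome, x$mediator, paste(x$exogenous, collapse = ", "),
              x$n))
  stars <- cut(x$effects$p, c(-Inf, 0.001, 0.01, Inf),
               labels = c("***", "**", ""))
  out <- cbind(x$effects[c("source", "kind")],
               round(x$effects[c("estimate", "se", "p")], 4),
               sig = as.character(stars))
  print(out, row.names = FALSE)
  invisible(x)
}

.effect_index <- function(model, source, kind) {
  if (source == model$mediator) {
    if (kind != "direct") stop("the mediator has only a direct effect")
    return(7L)
  }
  i <- match(source, model$exogenous)
  if (is.na(i)) stop("unknown effect source '", source, "'")
  if (!kind %in% c("direct", "indirect", "total"))
    stop("unknown effect kind '", kind, "'")
  (i - 1L) * 3L + match(kind, c("direct", "indirect", "total"))
}

#' Wald contrast between two effects of a path model
#'
#' Chi-square test of equality of two (possibly composite) effects, e.g.
#' the indirect effect of age versus the indirect effect of the hydraulic
#' variable: \eqn{\chi^2 = (e_a - e_b)^2 / var(e_a - e_b)} with the variance
#' from the delta method on the joint coefficient covariance (df = 1).
#'
#' @param model a [fit_path()] object.
#' @param a,b each a character vector \code{c(source, kind)} with kind one
#'   of \code{"direct"}, \code{"indirect"}, \code{"total"}.
#' @return object of class \code{wald_contrast}: \code{statistic},
#'   \code{df}, \code{p}, \code{description}, \code{difference}.
#' @export
wald_contrast <- function(model, a, b) {
  stopifnot(inherits(model, "path_model"),
            length(a) == 2L, length(b) == 2L)
  ia <- .effect_index(model, a[1], a[2])
  ib <- .effect_index(model, b[1], b[2])
  diff <- model$effects$estimate[ia] - model$effects$estimate[ib]
  V <- model$effects_vcov
  v <- V[ia, ia] + V[ib, ib] - 2 * V[ia, ib]
  same <- identical(a, b) || ia == ib
  if (v <= 0 && !same) stop("variance of the effect difference is zero")
  stat <- if (same) 0 else diff^2 / v
  structure(list(description = sprintf("%s(%s) vs %s(%s)",
                                       a[2], a[1], b[2], b[1]),
                 statistic = stat, df = 1L,
                 p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 difference = diff),
            class = "wald_contrast")
}

#' @export
print.wald_contrast <- function(x, ...) {
  cat(sprintf("Wald contrast %s: chi2 = %.3f (df = 1), p = %.4g\n",
              x$description, x$statistic, x$p))
  invisible(x)
}
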