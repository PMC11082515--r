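# Standardized major axis (SMA) regression, common-slope tests and
# conduit tapering.
#
# SMA treats x and y symmetrically: the slope is sign(r) * sd(y)/sd(x) and
# the line passes through the centroid. Confidence intervals and the
# common-slope likelihood-ratio test follow the residual/fitted-axis
# correlation formulation standard in allometry.

#' Standardized major axis fit
#'
#' Fits an SMA line, by default on natural-log-transformed variables (the
#' standard choice for allometric scaling). The slope is
#' \eqn{sign(r)\,sd(y)/sd(x)}; the intercept places the line through the
#' centroid. The slope confidence interval is
#' \eqn{b(\sqrt{B+1} \pm \sqrt{B})} with
#' \eqn{B = F_{1-\alpha}(1, n-2)(1-r^2)/(n-2)}.
#'
#' @param x,y numeric vectors; strictly positive when \code{log = TRUE}.
#' @param log if \code{TRUE} (default) fit on \code{ln(x)}, \code{ln(y)}.
#' @param alpha confidence level is \code{1 - alpha}.
#' @param x_label,y_label labels stored on the fit.
#' @return an object of class \code{sma_fit}: list with \code{slope},
#'   \code{intercept}, \code{r2}, \code{n}, \code{slope_ci}, \code{log},
#'   labels, and the (transformed) data.
#' @examples
#' fit <- sma_fit(c(1, 2, 3), c(1, 3, 5), log = FALSE)
#' fit$slope      # 2
#' @export
sma_fit <- function(x, y, log = TRUE, alpha = 0.05,
                    x_label = deparse1(substitute(x)),
                    y_label = deparse1(substitute(y))) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("SMA needs at least 3 complete observations")
  if (log) {
    if (any(x <= 0) || any(y <= 0))
      stop("log-scale SMA needs strictly positive x and y")
    x <- base::log(x); y <- base::log(y)
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  if (r == 0) stop("correlation is exactly zero: SMA slope sign undefined")
  slope <- sign(r) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B)))
  structure(list(slope = slope, intercept = intercept, r2 = r^2, n = n,
                 slope_ci = ci, alpha = alpha, log = log,
                 x_label = x_label, y_label = y_label, x = x, y = y),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat("Standardized major axis fit",
      if (x$log) "(ln-ln scale)" else "(raw scale)", "\n")
  cat(sprintf("  %s ~ %s, n = %d\n", x$y_label, x$x_label, x$n))
  cat(sprintf("  slope     %8.4f  [%.4f, %.4f]\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %8.4f\n  r^2       %8.4f\n", x$intercept, x$r2))
  invisible(x)
}

# correlation between SMA residual and fitted-axis scores at slope b
.sma_rf_cor <- function(x, y, b) stats::cor(y - b * x, y + b * x)

# profile objective for the common slope: sum_i w_i * ln(1 - r_i(b)^2),
# maximal (= 0) when every group's own SMA slope equals b; the weights are
# the degrees-of-freedom-corrected w_i = n_i - 2.5 (Warton-Weber), which
# keeps the chi-square reference calibrated at moderate group sizes
.common_slope_obj <- function(b, xs, ys, ns) {
  s <- 0
  for (i in seq_along(xs)) {
    r <- .sma_rf_cor(xs[[i]], ys[[i]], b)
    s <- s + ns[i] * base::log(max(1 - r^2, .Machine$double.xmin))
  }
  s
}

#' Likelihood-ratio test for a common SMA slope across groups
#'
#' Tests whether several groups share one SMA slope. Within each group the
#' residual scores \eqn{y - bx} are uncorrelated with the fitted-axis scores
#' \eqn{y + bx} exactly at the group's own SMA slope; the statistic
#' \eqn{-\sum_i n_i \ln(1 - r_i^2(\hat b))}, with \eqn{\hat b} the common
#' slope maximising the profile likelihood, is referred to a chi-square with
#' \code{g - 1} degrees of freedom. A residual-rotation permutation reference
#' is available as a cross-check (\code{n_perm > 0}).
#'
#' @param x,y numeric vectors (positive if \code{log = TRUE}).
#' @param group group labels, at least 2 levels with n >= 3 each.
#' @param log fit on the natural-log scale (default).
#' @param alpha level used for the per-group slope CIs.
#' @param n_perm number of within-group residual permutations for the
#'   permutation p-value (0 = skip).
#' @return object of class \code{common_slope_test}: \code{statistic},
#'   \code{df}, \code{p}, \code{common_slope}, \code{group_slopes}, and
#'   \code{p_perm} when requested.
#' @export
common_slope_test <- function(x, y, group, log = TRUE, alpha = 0.05,
                              n_perm = 0) {
  ok <- stats::complete.cases(x, y, group)
  x <- x[ok]; y <- y[ok]; group <- as.character(group[ok])
  levs <- unique(group)
  if (length(levs) < 2L) stop("at least 2 groups are required")
  fits <- lapply(levs, function(g)
    sma_fit(x[group == g], y[group == g], log = log, alpha = alpha,
            x_label = "x", y_label = "y"))
  names(fits) <- levs
  xs <- lapply(fits, `[[`, "x")  # already transformed
  ys <- lapply(fits, `[[`, "y")
  ns <- vapply(fits, `[[`, 0, "n") - 2.5
  slopes <- vapply(fits, `[[`, 0, "slope")

  lo <- min(slopes); hi <- max(slopes)
  pad <- max(abs(slopes)) * 0.5 + 1e-8
  opt <- stats::optimize(.common_slope_obj, interval = c(lo - pad, hi + pad),
                         xs = xs, ys = ys, ns = ns, maximum = TRUE,
                         tol = 1e-10)
  b_hat <- opt$maximum
  stat <- max(0, -opt$objective)
  df <- length(levs) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)

  p_perm <- NA_real_
  if (n_perm > 0) {
    # rotate to residual/fitted-axis scores at the common slope, permute the
    # residual scores within groups, rotate back, recompute the statistic
    us <- Map(function(xg, yg) yg - b_hat * xg, xs, ys)
    vs <- Map(function(xg, yg) yg + b_hat * xg, xs, ys)
    exceed <- 0L
    for (k in seq_len(n_perm)) {
      xs_p <- vector("list", length(xs)); ys_p <- xs_p
      for (i in seq_along(xs)) {
        up <- sample(us[[i]])
        ys_p[[i]] <- (up + vs[[i]]) / 2
        xs_p[[i]] <- (vs[[i]] - up) / (2 * b_hat)
      }
      sl_p <- vapply(seq_along(xs_p), function(i) {
        r <- stats::cor(xs_p[[i]], ys_p[[i]])
        sign(r) * stats::sd(ys_p[[i]]) / stats::sd(xs_p[[i]])
      }, 0)
      o_p <- stats::optimize(.common_slope_obj,
                             interval = range(sl_p) + c(-1, 1) *
                               (max(abs(sl_p)) * 0.5 + 1e-8),
                             xs = xs_p, ys = ys_p, ns = ns, maximum = TRUE,
                             tol = 1e-8)
      if (-o_p$objective >= stat) exceed <- exceed + 1L
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
  }

  structure(list(statistic = stat, df = df, p = p,
                 common_slope = b_hat, group_slopes = slopes,
                 p_perm = p_perm, n_perm = n_perm, fits = fits),
            class = "common_slope_test")
}

#' @export
print.common_slope_test <- function(x, ...) {
  cat("Common-slope likelihood-ratio test (SMA)\n")
  cat("  group slopes:",
      paste(sprintf("%s = %.4f", names(x$group_slopes), x$group_slopes),
            collapse = ", "), "\n")
  cat(sprintf("  common slope %.4f; LR = %.4f, df = %d, p = %.4g\n",
              x$common_slope, x$statistic, x$df, x$p))
  if (!is.na(x$p_perm))
    cat(sprintf("  permutation p (%d perms) = %.4g\n", x$n_perm, x$p_perm))
  invisible(x)
}

#' Tree-level conduit tapering
#'
#' The tapering index of xylem conduits for a single tree: the SMA slope of
#' hydraulically weighted vessel diameter against distance from the tree top,
#' by default on the ln-ln scale so the index is the exponent of the implied
#' power law. Discs very close to the top (where \code{ln L} degenerates)
#' are excluded.
#'
#' @param distance_from_top distances L (m) of the discs, > 0.
#' @param d_h hydraulically weighted diameters (um) of the same discs.
#' @param log use the ln-ln scale (default).
#' @param min_distance exclusion threshold for near-top discs (m); discs
#'   with \code{L < min_distance} are dropped from log-scale fits.
#' @param alpha CI level for the underlying SMA.
#' @return the SMA fit (class \code{sma_fit}) whose \code{slope} is the
#'   tapering index, or \code{NA} with a warning when fewer than 3 usable
#'   discs remain.
#' @export
conduit_taper <- function(distance_from_top, d_h, log = TRUE,
                          min_distance = 0.5, alpha = 0.05) {
  ok <- stats::complete.cases(distance_from_top, d_h)
  if (log) ok <- ok & distance_from_top >= min_distance
  L <- distance_from_top[ok]; dh <- d_h[ok]
  if (length(L) < 3L) {
    warning("fewer than 3 usable discs: conduit taper is NA")
    return(NA_real_)
  }
  sma_fit(L, dh, log = log, alpha = alpha,
          x_label = "distance_from_top", y_label = "d_h")
}
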