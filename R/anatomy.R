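# Derived wood and foliar traits.
#
# Unit conventions, enforced at the boundary everywhere in the package:
#   vessel axes        micrometres (um)
#   vessel density     per square millimetre (mm^-2)
#   radii              centimetres (cm)
#   areas              square centimetres (cm^2)
#   leaf areas         m^2 (total), cm^2 (mean per leaf)
#   stomatal density   mm^-2; stomatal size um^2

#' Hydraulically weighted vessel diameter for elliptical conduits
#'
#' Computes the hydraulically weighted diameter
#' \deqn{D_H = \left[\frac{1}{n}\sum_i \frac{2 a_i^3 b_i^3}{a_i^2+b_i^2}\right]^{1/4}}
#' from the major (\code{a}) and minor (\code{b}) Feret axes of each vessel.
#' For circular vessels (\code{a == b}) this reduces to the classical
#' fourth-power-mean hydraulic diameter.
#'
#' @param a numeric vector of major-axis diameters (um), all positive.
#' @param b numeric vector of minor-axis diameters (um), same length as
#'   \code{a}; defaults to \code{a} (circular vessels).
#' @return the hydraulically weighted diameter \code{D_H} in um (scalar).
#' @examples
#' hydraulic_diameter(c(50, 100))           # two circular vessels
#' hydraulic_diameter(120, 80)              # one elliptical vessel
#' @export
hydraulic_diameter <- function(a, b = a) {
  if (length(a) == 0L) stop("at least one vessel is required")
  if (length(b) != length(a)) stop("'a' and 'b' must have the same length")
  if (anyNA(a) || anyNA(b)) stop("vessel axes must not contain NA")
  if (any(a <= 0) || any(b <= 0)) stop("vessel axes must be positive")
  term <- 2 * a^3 * b^3 / (a^2 + b^2)
  mean(term)^0.25
}

#' Quadratic-mean radius of a cross-section
#'
#' The mean radius of an eccentric disc measured in eight equally spaced
#' directions, summarised as the quadratic (root-mean-square) average so that
#' \eqn{\pi r^2} recovers the cross-sectional area of the equivalent circle.
#'
#' @param r numeric vector of exactly 8 non-negative radii (cm).
#' @return quadratic-mean radius (cm). All-zero input (absent heartwood)
#'   returns 0.
#' @export
quadratic_mean_radius <- function(r) {
  if (length(r) != 8L) stop("exactly 8 radii are required, got ", length(r))
  if (anyNA(r)) stop("radii must not contain NA")
  if (any(r < 0)) stop("radii must be non-negative")
  sqrt(mean(r^2))
}

#' Physical constants for anatomical maximum stomatal conductance
#'
#' @param d_w diffusivity of water vapour in air (m^2 s^-1).
#' @param v molar volume of air (m^3 mol^-1).
#' @param pore_area_fraction fraction of the measured stomatal size treated
#'   as the fully open pore area, in (0, 1].
#' @param pore_depth_rule how stomatal pore depth is obtained:
#'   \code{"sqrt_amax_pi"} sets depth to the radius of the circle-equivalent
#'   pore, \code{sqrt(a_max/pi)}; \code{"constant"} uses \code{pore_depth}.
#' @param pore_depth pore depth in um, only used with rule \code{"constant"}.
#' @return an object of class \code{gmax_constants}.
#' @export
gmax_constants <- function(d_w = 2.49e-5, v = 0.0245,
                           pore_area_fraction = 0.12,
                           pore_depth_rule = c("sqrt_amax_pi", "constant"),
                           pore_depth = NULL) {
  pore_depth_rule <- match.arg(pore_depth_rule)
  if (!is.numeric(d_w) || d_w <= 0) stop("'d_w' must be positive")
  if (!is.numeric(v) || v <= 0) stop("'v' must be positive")
  if (!is.numeric(pore_area_fraction) || pore_area_fraction <= 0 ||
      pore_area_fraction > 1)
    stop("'pore_area_fraction' must be in (0, 1]")
  if (pore_depth_rule == "constant" &&
      (is.null(pore_depth) || pore_depth <= 0))
    stop("rule 'constant' needs a positive 'pore_depth' (um)")
  structure(list(d_w = d_w, v = v,
                 pore_area_fraction = pore_area_fraction,
                 pore_depth_rule = pore_depth_rule,
                 pore_depth = pore_depth),
            class = "gmax_constants")
}

#' Anatomical maximum stomatal conductance to water vapour
#'
#' Computes \eqn{G_{max} = (d_w/v)\, D_s\, a_{max} / (p_d + (\pi/2)\sqrt{a_{max}/\pi})}
#' with \eqn{a_{max}} the maximal pore area (a configurable fraction of the
#' measured stomatal size) and \eqn{p_d} the pore depth. \code{G_max} is
#' linear in stomatal density.
#'
#' @param stomatal_density stomatal density \code{D_s} (mm^-2), positive.
#' @param stomatal_size stomatal size \code{S} (um^2), positive.
#' @param constants a [gmax_constants()] object.
#' @return maximum stomatal conductance (mol m^-2 s^-1), vectorised over
#'   inputs.
#' @export
gmax <- function(stomatal_density, stomatal_size,
                 constants = gmax_constants()) {
  if (!inherits(constants, "gmax_constants"))
    stop("'constants' must be a gmax_constants object")
  if (any(stomatal_density <= 0)) stop("stomatal density must be positive")
  if (any(stomatal_size <= 0)) stop("stomatal size must be positive")
  d_si <- stomatal_density * 1e6        # mm^-2 -> m^-2
  amax <- constants$pore_area_fraction * stomatal_size * 1e-12  # um^2 -> m^2
  pd <- switch(constants$pore_depth_rule,
               sqrt_amax_pi = sqrt(amax / pi),
               constant = rep(constants$pore_depth * 1e-6, length(amax)))
  (constants$d_w / constants$v) * d_si * amax /
    (pd + (pi / 2) * sqrt(amax / pi))
}

qmean_cols <- function(df, prefix) {
  m <- as.matrix(df[paste0(prefix, 1:8)])
  sqrt(rowMeans(m^2))
}

#' Derived cross-sectional traits for every disc
#'
#' Computes, per disc: quadratic-mean stem and heartwood radii, sapwood
#' width, under-bark cross-sectional area, heartwood and sapwood areas,
#' heartwood proportion, growth rate, and (where a vessel sample exists)
#' hydraulically weighted diameter, mean vessel lumen area, vessel density,
#' vessel lumen fraction and total conductive vessel area.
#'
#' Areas are derived from the quadratic-mean radii via the circle formula, so
#' sapwood and heartwood areas close exactly on the stem area. Externally
#' measured areas can be passed through instead (\code{measured_areas}); the
#' function then checks closure of \code{SWa = CSa - HWa}.
#'
#' @param discs data.frame with columns \code{tree_id}, \code{disc_id},
#'   \code{stem_r1..stem_r8}, \code{hw_r1..hw_r8}, \code{cambial_age};
#'   additional columns are carried through.
#' @param vessels optional long data.frame with columns \code{tree_id},
#'   \code{disc_id}, \code{major}, \code{minor}, \code{vessel_density};
#'   discs without vessel rows get \code{NA} vessel traits (branch discs
#'   typically lack a vessel sample).
#' @param measured_areas optional data.frame \code{(tree_id, disc_id, csa,
#'   hwa)} of image-measured areas (cm^2) that replace the circle-formula
#'   areas; closure \code{SWa + HWa = CSa} still holds by construction and
#'   radii-implied areas are checked against them with a warning beyond
#'   \code{closure_tol} relative difference.
#' @param closure_tol relative tolerance for the measured-area check.
#' @return \code{discs} with the derived trait columns \code{s_r, hw_r_mean,
#'   sw_r, csa, hwa, swa, hw_proportion, gr, d_h, a_v, n_v, f_v, tcva}
#'   appended (units as in the package conventions).
#' @export
disc_traits <- function(discs, vessels = NULL, measured_areas = NULL,
                        closure_tol = 0.05) {
  stopifnot(is.data.frame(discs))
  need <- c("tree_id", "disc_id", paste0("stem_r", 1:8), paste0("hw_r", 1:8),
            "cambial_age")
  miss <- setdiff(need, names(discs))
  if (length(miss)) stop("missing disc columns: ", paste(miss, collapse = ", "))

  out <- discs
  out$s_r <- qmean_cols(discs, "stem_r")
  out$hw_r_mean <- qmean_cols(discs, "hw_r")
  stem_m <- as.matrix(discs[paste0("stem_r", 1:8)])
  hw_m <- as.matrix(discs[paste0("hw_r", 1:8)])
  if (any(hw_m > stem_m + 1e-9))
    stop("heartwood radius exceeds stem radius on disc ",
         out$disc_id[which(rowSums(hw_m > stem_m + 1e-9) > 0)[1]])
  out$sw_r <- out$s_r - out$hw_r_mean
  out$csa <- pi * out$s_r^2
  out$hwa <- pi * out$hw_r_mean^2

  if (!is.null(measured_areas)) {
    key <- paste(out$tree_id, out$disc_id)
    mkey <- paste(measured_areas$tree_id, measured_areas$disc_id)
    idx <- match(key, mkey)
    has <- !is.na(idx)
    rel <- abs(out$csa[has] - measured_areas$csa[idx[has]]) /
      measured_areas$csa[idx[has]]
    if (any(rel > closure_tol))
      warning(sum(rel > closure_tol),
              " disc(s) where radii-implied and measured stem areas differ by >",
              closure_tol * 100, "%")
    out$csa[has] <- measured_areas$csa[idx[has]]
    out$hwa[has] <- measured_areas$hwa[idx[has]]
  }

  out$swa <- out$csa - out$hwa
  if (any(out$swa < -1e-9)) stop("heartwood area exceeds stem area")
  out$hw_proportion <- out$hwa / out$csa
  if (any(out$cambial_age <= 0)) stop("cambial age must be positive")
  out$gr <- 2 * out$s_r / out$cambial_age

  out$d_h <- NA_real_
  out$a_v <- NA_real_
  out$n_v <- NA_real_
  if (!is.null(vessels) && nrow(vessels)) {
    vkey <- paste(vessels$tree_id, vessels$disc_id)
    okey <- paste(out$tree_id, out$disc_id)
    for (k in unique(vkey)) {
      i <- which(okey == k)
      if (!length(i)) next
      vs <- vessels[vkey == k, ]
      out$d_h[i] <- hydraulic_diameter(vs$major, vs$minor)
      out$a_v[i] <- mean(pi * vs$major * vs$minor / 4) / 1e6  # um^2 -> mm^2
      out$n_v[i] <- vs$vessel_density[1]
    }
  }
  out$f_v <- out$a_v * out$n_v * 100                  # % of sapwood section
  if (any(out$f_v >= 100, na.rm = TRUE))
    stop("vessel lumen fraction >= 100%: inconsistent vessel units")
  out$tcva <- out$a_v * out$n_v * out$swa             # cm^2
  out
}

#' Vertical profile of heartwood proportion within a tree
#'
#' Orders the trunk discs of one tree from base to top (decreasing distance
#' from the top, \code{L}) and reports the heartwood-area proportion profile
#' together with the sign of its Spearman trend against \code{L}.
#'
#' @param discs derived disc table (from [disc_traits()]) for a single tree,
#'   with columns \code{distance_from_top} and \code{hw_proportion}.
#' @return data.frame \code{(distance_from_top, hw_proportion)} sorted
#'   base-to-top, with attributes \code{trend} (sign of the Spearman
#'   correlation with \code{L}: 1, 0 or -1) and \code{rho}.
#' @export
hw_proportion_profile <- function(discs) {
  stopifnot(is.data.frame(discs))
  if (!all(c("distance_from_top", "hw_proportion") %in% names(discs)))
    stop("need columns 'distance_from_top' and 'hw_proportion'")
  if (nrow(discs) < 2L) stop("at least 2 trunk discs are required")
  ord <- order(discs$distance_from_top, decreasing = TRUE)
  prof <- discs[ord, c("distance_from_top", "hw_proportion")]
  rownames(prof) <- NULL
  rho <- if (stats::sd(prof$hw_proportion) == 0) 0 else
    suppressWarnings(stats::cor(prof$distance_from_top, prof$hw_proportion,
                                method = "spearman"))
  attr(prof, "rho") <- rho
  attr(prof, "trend") <- sign(round(rho, 12))
  prof
}
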