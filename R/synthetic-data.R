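# Seeded generator of two-cohort tree datasets (trees, trunk/branch discs,
# vessel samples, leaves, stomata) with the statistical structure the
# analysis assumes, plus the truth table used by parameter-recovery tests.
#
# Design, in brief:
#   * tree-level growth rate GR is lognormal (positivity); the diameter
#     trajectory is D(t) = GR * t, so the observed per-disc growth rate
#     2*S_R/cambial_age recovers the tree GR exactly;
#   * heartwood presence per disc is Bernoulli from the truth logistic
#     P = plogis(a + b*log(age) + c*log(GR));
#   * where present, HW_rg = round(hw_ring_rate * (age - onset_age)) clipped
#     to [1, age - 1], with onset_age the tree-level inflection point of the
#     truth logistic;
#   * heartwood area follows the truth power law in cambial age with
#     multiplicative lognormal noise and (optionally) a negative dependence
#     on the vessel lumen fraction, the hook that creates a *direct*
#     hydraulic effect on heartwood area in the path models;
#   * vessel major/minor axes are drawn so the per-disc hydraulically
#     weighted diameter matches the cohort mean/sd and tapers along the
#     distance from the tree top with the cohort-specific exponent;
#   * branch discs carry total leaf area growing linearly with branch age.
# All randomness flows from the single mandatory seed.

.lnorm_pars <- function(m, s) {
  # moment-matched lognormal: E = m, SD = s
  s2 <- base::log(1 + (s / m)^2)
  c(meanlog = base::log(m) - s2 / 2, sdlog = sqrt(s2))
}

.rlnorm_m <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  p <- .lnorm_pars(m, s)
  stats::rlnorm(n, p[1], p[2])
}

# multiplicative mean-one lognormal noise
.rnoise <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  stats::rlnorm(n, -sd^2 / 2, sd)
}

.noise_defaults <- function() {
  list(gr_disc = 0.08, dh = 0.02, vessel_size = 0.10, density = 0.15,
       hwa = 0.05, leaf_total = 0.25, stomata = 0.08, branch_gr = 0.20)
}

#' Configuration of one generated cohort
#'
#' Bundles every truth parameter of the generator for one cohort (shaded or
#' sun-exposed): sampling design, growth, heartwood-onset logistic,
#' ring-conversion and heartwood-area truths, vessel, leaf and stomatal
#' distributions, and the noise model. See [default_study_config()] for the
#' calibrated defaults.
#'
#' @param name cohort label, \code{"shaded"} or \code{"sun_exposed"}.
#' @param n_trees number of trees (>= 1).
#' @param age_range integer range of tree (base cambial) ages, years.
#' @param diameter_growth_rate_mean,diameter_growth_rate_sd mean and sd of
#'   the tree-level diameter growth rate (cm/yr), lognormally distributed.
#' @param disc_interval vertical spacing of trunk discs (m).
#' @param onset_logistic_a,onset_logistic_b,onset_logistic_c truth
#'   coefficients of the occurrence logistic in \code{log(age)} and
#'   \code{log(GR)}.
#' @param hw_ring_rate rings converted to heartwood per year after onset.
#' @param hw_area_power_a,hw_area_power_b truth power law
#'   \code{HWa = a * age^b} (cm^2).
#' @param hw_fv_exponent exponent of the vessel-lumen-fraction modifier on
#'   heartwood area (0 = none; negative values make well-conducting stems
#'   keep more sapwood, creating a direct hydraulic path effect).
#' @param vessel_dh_mean,vessel_dh_sd tree-level mean/sd of the
#'   hydraulically weighted vessel diameter (um).
#' @param vessel_density_mean,vessel_density_sd vessel density (mm^-2).
#' @param vessel_ellipticity minor/major axis ratio of vessels, in (0, 1].
#' @param conduit_taper truth exponent of D_H against distance from the
#'   tree top (ln-ln scale).
#' @param vessels_per_disc vessels measured per trunk disc.
#' @param leaf_area_mean,leaf_area_sd tree-level mean leaf (leaflet) area
#'   a_L (cm^2).
#' @param leaf_area_rate slope of branch total leaf area A_L on branch
#'   cambial age (m^2/yr).
#' @param branches_per_tree branch discs collected per tree.
#' @param stomatal_density_mean stomatal density (mm^-2).
#' @param stomatal_size_mean stomatal size (um^2).
#' @param noise_sd named list of lognormal noise sds (see
#'   \code{heartwoodkit:::.noise_defaults}); partial lists are completed
#'   with the defaults.
#' @param eccentricity_cv relative sd of the 8 radii around the
#'   cross-section mean (stem eccentricity).
#' @param height_coef,height_exp total height allometry
#'   \code{H = coef * D^exp} (m, D in cm).
#' @param trunk_fraction trunk height as a fraction of total height.
#' @param branch_gr_fraction branch growth rate as a fraction of the tree
#'   growth rate.
#' @param stem_taper_exponent within-tree exponent of stem radius on
#'   cambial age (radius ~ cambial^gamma), in (0, 1]; values below 1 give
#'   the flatter-than-linear stem profiles real trunks show.
#' @return an object of class \code{cohort_config}.
#' @export
cohort_config <- function(name,
                          n_trees,
                          age_range,
                          diameter_growth_rate_mean,
                          diameter_growth_rate_sd,
                          disc_interval,
                          onset_logistic_a,
                          onset_logistic_b,
                          onset_logistic_c,
                          hw_ring_rate,
                          hw_area_power_a,
                          hw_area_power_b,
                          hw_fv_exponent = 0,
                          vessel_dh_mean,
                          vessel_dh_sd,
                          vessel_density_mean,
                          vessel_density_sd,
                          vessel_ellipticity = 0.85,
                          conduit_taper = 0,
                          vessels_per_disc = 30L,
                          leaf_area_mean,
                          leaf_area_sd,
                          leaf_area_rate,
                          branches_per_tree = 10L,
                          stomatal_density_mean,
                          stomatal_size_mean,
                          noise_sd = list(),
                          eccentricity_cv = 0.06,
                          height_coef = 2.5,
                          height_exp = 0.65,
                          trunk_fraction = 0.65,
                          branch_gr_fraction = 0.35,
                          stem_taper_exponent = 0.7) {
  ns <- utils::modifyList(.noise_defaults(), noise_sd)
  cfg <- structure(mget(setdiff(names(formals(cohort_config)), "noise_sd")),
                   class = "cohort_config")
  cfg$noise_sd <- ns
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants: positive counts, rates, areas and
#' densities, ellipticity in (0, 1], positive disc interval, an age range
#' wide and old enough to host discs.
#'
#' @param config a [cohort_config()] object.
#' @return the config, invisibly; errors describe the offending field.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with(config, {
    if (!is.numeric(n_trees) || n_trees < 1) stop("n_trees must be >= 1")
    if (length(age_range) != 2L || diff(age_range) < 0 || age_range[1] < 3)
      stop("age_range must be an increasing pair of ages >= 3 years")
    pos <- c(diameter_growth_rate_mean = diameter_growth_rate_mean,
             disc_interval = disc_interval,
             hw_ring_rate = hw_ring_rate,
             hw_area_power_a = hw_area_power_a,
             vessel_dh_mean = vessel_dh_mean,
             vessel_density_mean = vessel_density_mean,
             leaf_area_mean = leaf_area_mean,
             leaf_area_rate = leaf_area_rate,
             stomatal_density_mean = stomatal_density_mean,
             stomatal_size_mean = stomatal_size_mean,
             height_coef = height_coef, height_exp = height_exp,
             trunk_fraction = trunk_fraction,
             branch_gr_fraction = branch_gr_fraction,
             vessels_per_disc = vessels_per_disc,
             branches_per_tree = branches_per_tree)
    if (any(pos <= 0))
      stop("non-positive parameter(s): ",
           paste(names(pos)[pos <= 0], collapse = ", "))
    nonneg <- c(diameter_growth_rate_sd, vessel_dh_sd, vessel_density_sd,
                leaf_area_sd, eccentricity_cv, unlist(noise_sd))
    if (any(nonneg < 0)) stop("noise/sd parameters must be non-negative")
    if (vessel_ellipticity <= 0 || vessel_ellipticity > 1)
      stop("vessel_ellipticity must be in (0, 1]")
    if (stem_taper_exponent <= 0 || stem_taper_exponent > 1)
      stop("stem_taper_exponent must be in (0, 1]")
    if (onset_logistic_b <= 0)
      stop("onset_logistic_b must be positive (occurrence increases with age)")
    # the smallest, slowest tree must still host >= 2 trunk discs
    d_min <- max(diameter_growth_rate_mean - 2 * diameter_growth_rate_sd,
                 0.25 * diameter_growth_rate_mean) * age_range[1]
    h_min <- trunk_fraction * height_coef * d_min^height_exp
    if (h_min < 0.3 + 2 * disc_interval)
      stop("ages too small to host at least two trunk discs at this ",
           "disc_interval")
  })
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config '%s': %d trees, ages %d-%d yr, GR %.2f +/- %.2f cm/yr\n",
              x$name, x$n_trees, x$age_range[1], x$age_range[2],
              x$diameter_growth_rate_mean, x$diameter_growth_rate_sd))
  cat(sprintf("  onset logistic (a, b, c) = (%.2f, %.2f, %.2f); ring rate %.2f /yr\n",
              x$onset_logistic_a, x$onset_logistic_b, x$onset_logistic_c,
              x$hw_ring_rate))
  cat(sprintf("  HWa = %.3g * age^%.2f; D_H %.1f +/- %.1f um, taper %.2f\n",
              x$hw_area_power_a, x$hw_area_power_b, x$vessel_dh_mean,
              x$vessel_dh_sd, x$conduit_taper))
  invisible(x)
}

#' Default two-cohort study configuration
#'
#' The study conditions the package emulates: a slower-growing shaded cohort
#' (7 trees, trunk discs every 1 m, mean diameter growth 0.30 cm/yr) and a
#' faster-growing sun-exposed cohort (10 trees, discs every 2 m, 1.02
#' cm/yr), with trait distributions calibrated to the measured cohort
#' contrasts (hydraulic diameter 101.33 vs 123.55 um, vessel density 18.06
#' vs 17.26 mm^-2, mean leaf area 33.82 vs 9.73 cm^2, branch leaf-area
#' accumulation 0.5 vs 3.5 m^2/yr, conduit tapering -0.29 vs 0.15). The
#' onset-logistic truth is solved from the age thresholds 15.8 yr at
#' GR = 0.30 and 12.0 yr at GR = 1.02; ring-conversion truths are 1.04
#' (shaded) and 0.96 (sun) rings/yr, and the heartwood-area power exponents
#' (4.68 vs 1.80) encode the 2.6-fold steeper heartwood-age scaling of
#' shaded trees. Only the shaded cohort carries a direct (negative) vessel-
#' lumen-fraction effect on heartwood area.
#'
#' @return named list with elements \code{shaded} and \code{sun_exposed},
#'   both [cohort_config()] objects.
#' @export
default_study_config <- function() {
  onset_a <- -19.92; onset_b <- 8; onset_c <- 1.8
  list(
    shaded = cohort_config(
      name = "shaded", n_trees = 7, age_range = c(45L, 60L),
      diameter_growth_rate_mean = 0.30, diameter_growth_rate_sd = 0.05,
      disc_interval = 1,
      onset_logistic_a = onset_a, onset_logistic_b = onset_b,
      onset_logistic_c = onset_c,
      hw_ring_rate = 1.04,
      hw_area_power_a = 5e-7, hw_area_power_b = 4.68,
      hw_fv_exponent = -0.35,
      vessel_dh_mean = 101.33, vessel_dh_sd = 9.67,
      vessel_density_mean = 18.06, vessel_density_sd = 3.27,
      conduit_taper = -0.29,
      leaf_area_mean = 33.82, leaf_area_sd = 4.98,
      leaf_area_rate = 0.5,
      stomatal_density_mean = 480, stomatal_size_mean = 130),
    sun_exposed = cohort_config(
      name = "sun_exposed", n_trees = 10, age_range = c(45L, 60L),
      diameter_growth_rate_mean = 1.02, diameter_growth_rate_sd = 0.15,
      disc_interval = 2,
      onset_logistic_a = onset_a, onset_logistic_b = onset_b,
      onset_logistic_c = onset_c,
      hw_ring_rate = 0.96,
      hw_area_power_a = 0.65, hw_area_power_b = 1.80,
      hw_fv_exponent = 0,
      vessel_dh_mean = 123.55, vessel_dh_sd = 8.81,
      vessel_density_mean = 17.26, vessel_density_sd = 2.82,
      conduit_taper = 0.15,
      leaf_area_mean = 9.73, leaf_area_sd = 1.28,
      leaf_area_rate = 3.5,
      stomatal_density_mean = 700, stomatal_size_mean = 130))
}

# draw 8 radii with multiplicative eccentricity noise, rescaled so their
# quadratic mean equals the target exactly
.draw_radii <- function(target, cv) {
  if (target == 0) return(rep(0, 8))
  e <- stats::rlnorm(8, 0, cv)
  target * e / sqrt(mean(e^2))
}

# vessel sample whose Eq.-1 hydraulic diameter targets dh_target
.draw_vessels <- function(n, dh_target, ellipticity, sigma) {
  k <- (2 * ellipticity^3 / (1 + ellipticity^2))^0.25
  a_c <- dh_target / k * exp(-2 * sigma^2)   # corrects 4th-moment bias
  a <- stats::rlnorm(n, base::log(a_c), sigma)
  b <- pmin(a, a * ellipticity * stats::rlnorm(n, 0, 0.03))
  data.frame(major = a, minor = b)
}

#' Generate one cohort of trees, discs, vessels, leaves and stomata
#'
#' Draws a complete seeded dataset for one cohort under the generative model
#' described in [cohort_config()]. Identical \code{(config, seed)} pairs
#' yield identical tables.
#'
#' @param config a validated [cohort_config()].
#' @param seed integer seed (mandatory; there is no hidden global
#'   randomness).
#' @return object of class \code{hw_dataset}: list of data.frames
#'   \code{trees}, \code{discs}, \code{vessels}, \code{leaves},
#'   \code{stomata} and the \code{truth} list (full config plus seed).
#' @export
generate_cohort <- function(config, seed) {
  validate_cohort_config(config)
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is mandatory")
  set.seed(as.integer(seed))
  ns <- config$noise_sd

  trees <- list(); discs <- list(); vessels <- list()
  leaves <- list(); stomata <- list()
  for (i in seq_len(config$n_trees)) {
    tid <- sprintf("%s_%02d", config$name, i)
    age <- sample(seq(config$age_range[1], config$age_range[2]), 1)
    gr <- .rlnorm_m(1, config$diameter_growth_rate_mean,
                    config$diameter_growth_rate_sd)
    d_base <- gr * age
    H <- config$height_coef * d_base^config$height_exp
    h <- config$trunk_fraction * H
    dbh <- gr * age * max(1 - 1.3 / H, 0.05)
    crown <- .draw_radii(0.15 * H, 0.2)
    trees[[i]] <- data.frame(
      tree_id = tid, cohort = config$name, age = age, gr_true = gr,
      dbh = dbh, total_height = H, trunk_height = h,
      t(stats::setNames(crown, paste0("crown_r", 1:8))))

    # ---- trunk discs
    zs <- seq(0.3, h, by = config$disc_interval)
    cambial <- pmax(2L, as.integer(round(age * (1 - zs / H))))
    keep <- !duplicated(cambial)          # rounding can collide near the top
    zs <- zs[keep]; cambial <- cambial[keep]
    if (length(zs) < 2L)
      stop("tree of age ", age, " hosts fewer than two trunk discs; ",
           "check age_range / disc_interval")
    nd <- length(zs)
    L <- H - zs
    # stem radius tapers sublinearly in cambial age within the tree
    # (S_R ~ cambial^gamma, gamma < 1, as real stems do), so the per-disc
    # growth rate 2*S_R/cambial_age rises toward the top; the taper factor
    # is mean-normalised per tree so the tree-level mean disc growth rate
    # stays calibrated to the cohort truth. The occurrence draw uses the
    # same per-disc rate the radii encode, so the observed growth rate is
    # exactly the logistic's GR covariate.
    grfac <- (cambial / age)^(config$stem_taper_exponent - 1)
    grfac <- grfac / mean(grfac)
    gr_disc <- gr * grfac * .rnoise(nd, ns$gr_disc)
    s_r <- gr_disc * cambial / 2
    p_hw <- stats::plogis(config$onset_logistic_a +
                            config$onset_logistic_b * base::log(cambial) +
                            config$onset_logistic_c * base::log(gr_disc))
    hw_present <- stats::rbinom(nd, 1, p_hw) == 1
    onset_age <- exp(-(config$onset_logistic_a +
                         config$onset_logistic_c * base::log(gr_disc)) /
                       config$onset_logistic_b)
    hw_rings <- ifelse(hw_present,
                       pmin(pmax(round(config$hw_ring_rate *
                                         (cambial - onset_age)), 1),
                            cambial - 1L), 0L)
    trunk <- data.frame(
      tree_id = tid, disc_id = sprintf("%s_T%02d", tid, seq_len(nd)),
      cohort = config$name, disc_type = "trunk",
      height_above_ground = zs, distance_from_top = L,
      cambial_age = cambial, hw_rings = as.integer(hw_rings),
      sw_rings = as.integer(cambial - hw_rings),
      hw_present = hw_present, gr_disc = gr_disc, gr_stem = gr,
      stringsAsFactors = FALSE)
    sr_mat <- t(vapply(s_r, .draw_radii, numeric(8),
                       cv = config$eccentricity_cv))
    colnames(sr_mat) <- paste0("stem_r", 1:8)
    trunk <- cbind(trunk, sr_mat)

    # ---- vessels on trunk discs, hydraulic diameter tapering along L
    dh_tree <- .rlnorm_m(1, config$vessel_dh_mean, config$vessel_dh_sd)
    f <- (L / exp(mean(base::log(L))))^config$conduit_taper
    f <- f / mean(f)                      # per-tree mean stays calibrated
    dh_disc <- dh_tree * f * .rnoise(nd, ns$dh)
    nv_tree <- .rlnorm_m(1, config$vessel_density_mean,
                         config$vessel_density_sd)
    nv_disc <- nv_tree * .rnoise(nd, ns$density)
    vt <- lapply(seq_len(nd), function(j) {
      vs <- .draw_vessels(config$vessels_per_disc, dh_disc[j],
                          config$vessel_ellipticity, ns$vessel_size)
      data.frame(tree_id = tid, disc_id = trunk$disc_id[j],
                 vessel_id = seq_len(nrow(vs)),
                 major = vs$major, minor = vs$minor,
                 vessel_density = nv_disc[j], stringsAsFactors = FALSE)
    })
    vessels[[i]] <- do.call(rbind, vt)

    # ---- branch discs and leaves
    nb <- config$branches_per_tree
    b_age <- pmax(2L, sample(seq(2L, max(3L, floor(age / 2))), nb,
                             replace = TRUE))
    gr_b <- gr * config$branch_gr_fraction * .rnoise(nb, ns$branch_gr)
    zb <- stats::runif(nb, h, 0.97 * H)
    p_hw_b <- stats::plogis(config$onset_logistic_a +
                              config$onset_logistic_b * base::log(b_age) +
                              config$onset_logistic_c * base::log(gr_b))
    hw_present_b <- stats::rbinom(nb, 1, p_hw_b) == 1
    onset_b <- exp(-(config$onset_logistic_a +
                       config$onset_logistic_c * base::log(gr_b)) /
                     config$onset_logistic_b)
    hw_rings_b <- ifelse(hw_present_b,
                         pmin(pmax(round(config$hw_ring_rate *
                                           (b_age - onset_b)), 1),
                              b_age - 1L), 0L)
    branch <- data.frame(
      tree_id = tid, disc_id = sprintf("%s_B%02d", tid, seq_len(nb)),
      cohort = config$name, disc_type = "branch",
      height_above_ground = zb, distance_from_top = H - zb,
      cambial_age = b_age, hw_rings = as.integer(hw_rings_b),
      sw_rings = as.integer(b_age - hw_rings_b),
      hw_present = hw_present_b, gr_disc = gr_b, gr_stem = gr_b,
      stringsAsFactors = FALSE)
    sb_mat <- t(vapply(gr_b * b_age / 2, .draw_radii, numeric(8),
                       cv = config$eccentricity_cv))
    colnames(sb_mat) <- paste0("stem_r", 1:8)
    branch <- cbind(branch, sb_mat)
    discs[[i]] <- rbind(trunk, branch)

    a_l_tree <- .rlnorm_m(1, config$leaf_area_mean, config$leaf_area_sd)
    A_L <- config$leaf_area_rate * b_age * .rnoise(nb, ns$leaf_total)
    n_leaves <- pmax(1L, as.integer(round(A_L * 1e4 / a_l_tree)))
    A_L <- n_leaves * a_l_tree / 1e4       # closes a_L * n = A_L exactly
    leaves[[i]] <- data.frame(
      tree_id = tid, branch_id = branch$disc_id, branch_age = b_age,
      n_leaves = n_leaves, total_leaf_area = A_L, mean_leaf_area = a_l_tree,
      green_mass = A_L * 1e4 * 0.020 * .rnoise(nb, 0.05),
      dry_mass = A_L * 1e4 * 0.008 * .rnoise(nb, 0.05),
      stringsAsFactors = FALSE)

    stomata[[i]] <- data.frame(
      tree_id = tid, leaf_id = sprintf("%s_L%d", tid, 1:3),
      stomatal_density = config$stomatal_density_mean * .rnoise(3, ns$stomata),
      stomatal_size = config$stomatal_size_mean * .rnoise(3, ns$stomata),
      stringsAsFactors = FALSE)
  }

  trees <- do.call(rbind, trees)
  discs <- do.call(rbind, discs)
  vessels <- do.call(rbind, vessels)
  leaves <- do.call(rbind, leaves)
  stomata <- do.call(rbind, stomata)

  # ---- second pass: heartwood areas and radii (depend on the cohort-level
  # vessel lumen fraction and, for branches, on the leaf-area residual)
  av_disc <- tapply(pi * vessels$major * vessels$minor / 4 / 1e6,
                    vessels$disc_id, mean)
  nv_by_disc <- tapply(vessels$vessel_density, vessels$disc_id, `[`, 1)
  fv <- av_disc[discs$disc_id] * nv_by_disc[discs$disc_id] * 100
  fv_ref <- stats::median(fv, na.rm = TRUE)
  lratio <- rep(1, nrow(discs))
  bidx <- match(discs$disc_id, leaves$branch_id)
  has_leaf <- !is.na(bidx)
  lratio[has_leaf] <- leaves$total_leaf_area[bidx[has_leaf]] /
    (config$leaf_area_rate * leaves$branch_age[bidx[has_leaf]])

  # heartwood area: truth power law in cambial age, with an amplitude
  # proportional to the squared lifetime growth rate of the stem (trunk:
  # tree rate; branch: branch rate) relative to the cohort mean -- heartwood
  # is an area, so faster-grown (wider) stems of the same age hold
  # proportionally more of it, and branch discs stay size-consistent.
  # The within-stem age exponent remains exactly hw_area_power_b.
  amp <- (discs$gr_stem / config$diameter_growth_rate_mean)^2
  hwa <- config$hw_area_power_a * amp *
    discs$cambial_age^config$hw_area_power_b *
    .rnoise(nrow(discs), ns$hwa)
  mod <- ifelse(is.na(fv), lratio, fv / fv_ref)
  hwa <- hwa * mod^config$hw_fv_exponent
  s_r_q <- qmean_cols(discs, "stem_r")
  hwa <- pmin(hwa, 0.85 * pi * s_r_q^2)
  hwa[!discs$hw_present] <- 0
  discs$gr_stem <- NULL
  hw_r_target <- sqrt(hwa / pi)
  hw_mat <- t(vapply(hw_r_target, .draw_radii, numeric(8),
                     cv = config$eccentricity_cv))
  stem_mat <- as.matrix(discs[paste0("stem_r", 1:8)])
  hw_mat <- pmin(hw_mat, stem_mat)        # pairwise containment
  colnames(hw_mat) <- paste0("hw_r", 1:8)
  discs <- cbind(discs, hw_mat)
  rownames(discs) <- NULL
  rownames(trees) <- NULL

  structure(list(trees = trees, discs = discs, vessels = vessels,
                 leaves = leaves, stomata = stomata,
                 truth = c(unclass(config), list(seed = as.integer(seed)))),
            class = "hw_dataset")
}

#' Generate the full two-cohort study dataset
#'
#' Runs [generate_cohort()] for each cohort with sub-seeds derived
#' deterministically from \code{seed} and binds the tables.
#'
#' @param configs named list of [cohort_config()] objects (default:
#'   [default_study_config()]).
#' @param seed integer master seed.
#' @return an object of class \code{hw_dataset} with combined tables and a
#'   per-cohort \code{truth} list.
#' @export
generate_study <- function(configs = default_study_config(), seed) {
  if (missing(seed)) stop("an integer seed is mandatory")
  sub <- (as.integer(seed) %% 100000000L) * 10L + seq_along(configs)
  parts <- Map(generate_cohort, configs, sub)
  out <- list()
  for (tab in c("trees", "discs", "vessels", "leaves", "stomata"))
    out[[tab]] <- do.call(rbind, c(lapply(parts, `[[`, tab),
                                   make.row.names = FALSE))
  out$truth <- c(lapply(parts, `[[`, "truth"), list(seed = as.integer(seed)))
  structure(out, class = "hw_dataset")
}

#' @export
print.hw_dataset <- function(x, ...) {
  cat("Synthetic heartwood study dataset\n")
  cat(sprintf("  %d trees (%s), %d discs (%d trunk / %d branch), %d vessels\n",
              nrow(x$trees),
              paste(sprintf("%s: %d", names(table(x$trees$cohort)),
                            table(x$trees$cohort)), collapse = ", "),
              nrow(x$discs), sum(x$discs$disc_type == "trunk"),
              sum(x$discs$disc_type == "branch"), nrow(x$vessels)))
  invisible(x)
}
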