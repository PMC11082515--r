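# End-to-end pipeline: simulate -> derive -> onset -> dynamics -> sma ->
# path models -> cohort-contrast report.

.kw_stat <- function(values, group) {
  # rank-sum H with tie correction; the permutation loop uses this directly
  r <- rank(values)
  N <- length(values)
  Rg <- tapply(r, group, sum)
  ng <- tapply(r, group, length)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(0)
  H / corr
}

#' Kruskal-Wallis rank test with a permutation option
#'
#' Tie-corrected Kruskal-Wallis H comparing two or more groups, with the
#' usual chi-square reference and an optional permutation p-value obtained
#' by shuffling group labels (the small-sample exact reference).
#'
#' @param values numeric observations.
#' @param group group labels (>= 2 levels).
#' @param n_perm number of label permutations (0 = chi-square only).
#' @return list \code{(statistic, df, p, p_perm)}.
#' @export
kruskal_wallis <- function(values, group, n_perm = 0) {
  ok <- stats::complete.cases(values, group)
  values <- values[ok]; group <- factor(group[ok])
  if (nlevels(group) < 2L) stop("at least 2 groups are required")
  if (length(values) < 3L) stop("at least 3 observations are required")
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, df = nlevels(group) - 1L, p = 1,
                p_perm = if (n_perm > 0) 1 else NA_real_))
  }
  kt <- stats::kruskal.test(values, group)
  out <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
              p = kt$p.value, p_perm = NA_real_)
  if (n_perm > 0) {
    obs <- .kw_stat(values, group)
    exceed <- sum(vapply(seq_len(n_perm), function(i)
      .kw_stat(values, sample(group)) >= obs - 1e-12, TRUE))
    out$p_perm <- (exceed + 1) / (n_perm + 1)
  }
  out
}

#' Pipeline run configuration
#'
#' @param seed mandatory integer seed driving every random draw.
#' @param cohorts named list of [cohort_config()]s
#'   (default [default_study_config()]).
#' @param alpha significance level for tests and CIs.
#' @param gr_split growth-rate value (cm/yr) splitting slower from faster
#'   growing stems for threshold reporting; thresholds of the growth-rate
#'   occurrence model are evaluated at the class medians.
#' @param out_dir optional directory; when given, result tables are written
#'   there as CSV.
#' @param stages character vector of stages to run (dependencies of a
#'   requested stage always run).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed, cohorts = default_study_config(),
                       alpha = 0.05, gr_split = 0.55, out_dir = NULL,
                       stages = c("onset", "dynamics", "sma", "path",
                                  "report")) {
  if (missing(seed)) stop("an integer seed is mandatory")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  lapply(cohorts, validate_cohort_config)
  structure(list(seed = as.integer(seed), cohorts = cohorts, alpha = alpha,
                 gr_split = gr_split, out_dir = out_dir, stages = stages),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.letters_from_p <- function(p, alpha) if (p < alpha) c("a", "b") else c("a", "a")

.onset_stage <- function(derived, alpha, gr_split) {
  rows <- list()
  thr_row <- function(fit, label, cov_value, thr) {
    ses <- sqrt(diag(fit$vcov))
    data.frame(model = fit$predictor_spec, evaluated_at = label,
               a = fit$a, b = fit$b, c = fit$c,
               se_a = ses[1], se_b = ses[2],
               se_c = if (length(ses) > 2) ses[3] else NA_real_,
               loglik = fit$loglik, n = fit$n,
               threshold = thr$point, ci_low = thr$ci_low,
               ci_high = thr$ci_high, scale = thr$scale,
               stringsAsFactors = FALSE)
  }
  f_d <- fit_occurrence(derived, "diameter", "none")
  f_a <- fit_occurrence(derived, "age", "none")
  f_ds <- fit_occurrence(derived, "diameter", "site")
  f_ag <- fit_occurrence(derived, "age", "gr")
  rows$d <- thr_row(f_d, "all", NULL, onset_threshold(f_d, alpha = alpha))
  rows$a <- thr_row(f_a, "all", NULL, onset_threshold(f_a, alpha = alpha))
  rows$ds0 <- thr_row(f_ds, "site=0", 0,
                      onset_threshold(f_ds, 0, alpha = alpha))
  rows$ds1 <- thr_row(f_ds, "site=1", 1,
                      onset_threshold(f_ds, 1, alpha = alpha))
  slow <- stats::median(derived$gr[derived$gr <= gr_split], na.rm = TRUE)
  fast <- stats::median(derived$gr[derived$gr > gr_split], na.rm = TRUE)
  rows$ag_slow <- thr_row(f_ag, sprintf("gr<=%.2f (median %.3f)", gr_split,
                                        slow), slow,
                          onset_threshold(f_ag, slow, alpha = alpha))
  rows$ag_fast <- thr_row(f_ag, sprintf("gr>%.2f (median %.3f)", gr_split,
                                        fast), fast,
                          onset_threshold(f_ag, fast, alpha = alpha))
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  lrt_site <- covariate_lrt(f_ds, f_d)
  lrt_gr <- covariate_lrt(f_ag, f_a)
  list(table = tab,
       lrt = data.frame(test = c("site in diameter model",
                                 "logGR in age model"),
                        chi2 = c(lrt_site$chi2, lrt_gr$chi2),
                        df = c(lrt_site$df, lrt_gr$df),
                        p = c(lrt_site$p, lrt_gr$p)),
       fits = list(diameter = f_d, age = f_a, diameter_site = f_ds,
                   age_gr = f_ag),
       thresholds = list(age_slow = rows$ag_slow$threshold,
                         age_fast = rows$ag_fast$threshold,
                         diam_shaded = rows$ds0$threshold,
                         diam_sun = rows$ds1$threshold))
}

.dynamics_stage <- function(derived, alpha) {
  trunk <- derived[derived$disc_type == "trunk" & derived$hw_present, ]
  trunk$diameter <- 2 * trunk$s_r
  specs <- list(
    list(resp = "hwa", pred = "cambial_age"),
    list(resp = "hwa", pred = "diameter"),
    list(resp = "hw_proportion", pred = "cambial_age"),
    list(resp = "hw_rings", pred = "cambial_age"))
  fams <- c("linear", "quadratic", "power", "asym_exp")
  rows <- list(); extras <- list()
  for (sp in specs) {
    x <- trunk[[sp$pred]]; y <- trunk[[sp$resp]]
    fits <- lapply(fams, function(f)
      tryCatch(fit_family(x, y, f), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    sel <- select_model(fits)
    by_c <- lapply(split(trunk, trunk$cohort), function(d)
      fit_family(d[[sp$pred]], d[[sp$resp]], sel$chosen))
    shared <- fit_family(x, y, sel$chosen)
    lrt <- group_lrt(shared, by_c)
    for (f in fits)
      rows[[length(rows) + 1L]] <- data.frame(
        response = sp$resp, predictor = sp$pred, family = f$family,
        a0 = f$params[["a0"]], a1 = f$params[["a1"]],
        a2 = if ("a2" %in% names(f$params)) f$params[["a2"]] else NA_real_,
        rse = f$rse, n = f$n, chosen = f$family == sel$chosen,
        group_lrt_chi2 = if (f$family == sel$chosen) lrt$chi2 else NA_real_,
        group_lrt_df = if (f$family == sel$chosen) lrt$df else NA_integer_,
        group_lrt_p = if (f$family == sel$chosen) lrt$p else NA_real_,
        stringsAsFactors = FALSE)
    extras[[paste(sp$resp, sp$pred, sep = "~")]] <-
      list(selection = sel, by_cohort = by_c, lrt = lrt)
  }
  # cohort-wise ring conversion and first-ring age (linear HW_rg ~ age)
  ring <- lapply(split(trunk, trunk$cohort), function(d) {
    fit <- fit_family(d$cambial_age, d$hw_rings, "linear")
    fra <- first_ring_age(fit, crossing = 0, alpha = alpha)
    list(fit = fit, first_ring = fra)
  })
  ring_tab <- do.call(rbind, lapply(names(ring), function(ch)
    data.frame(cohort = ch,
               ring_rate = ring[[ch]]$fit$params[["a1"]],
               ring_rate_se = ring[[ch]]$fit$param_ses[["a1"]],
               first_ring_age = ring[[ch]]$first_ring$age,
               first_ring_ci_low = ring[[ch]]$first_ring$ci_low,
               first_ring_ci_high = ring[[ch]]$first_ring$ci_high,
               stringsAsFactors = FALSE)))
  # power-law exponents of HWa ~ age per cohort (heartwood investment rate)
  pw <- lapply(split(trunk, trunk$cohort), function(d)
    fit_family(d$cambial_age, d$hwa, "power"))
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       ring = ring_tab, power_by_cohort = pw, details = extras)
}

.sma_stage <- function(derived, cohorts, alpha) {
  trunk <- derived[derived$disc_type == "trunk", ]
  responses <- c("s_r", "sw_r", "hw_r_mean", "csa", "swa", "hwa", "d_h",
                 "tcva")
  rows <- list()
  for (resp in responses) {
    per <- list(); ok_groups <- TRUE
    for (ch in names(cohorts)) {
      d <- trunk[trunk$cohort == cohorts[[ch]]$name, ]
      keep <- d$distance_from_top >= 0.5 * cohorts[[ch]]$disc_interval &
        !is.na(d[[resp]]) & d[[resp]] > 0
      d <- d[keep, ]
      per[[ch]] <- if (nrow(d) >= 3)
        sma_fit(d$distance_from_top, d[[resp]], log = TRUE, alpha = alpha,
                x_label = "L", y_label = resp) else NULL
      if (is.null(per[[ch]])) ok_groups <- FALSE
    }
    cst <- NULL
    if (ok_groups) {
      keep <- trunk$distance_from_top > 0 & !is.na(trunk[[resp]]) &
        trunk[[resp]] > 0
      d <- trunk[keep, ]
      cst <- tryCatch(common_slope_test(d$distance_from_top, d[[resp]],
                                        d$cohort, log = TRUE, alpha = alpha),
                      error = function(e) NULL)
    }
    lets <- if (!is.null(cst)) .letters_from_p(cst$p, alpha) else c(NA, NA)
    i <- 0
    for (ch in names(cohorts)) {
      i <- i + 1
      f <- per[[ch]]
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, cohort = cohorts[[ch]]$name,
        intercept = if (!is.null(f)) f$intercept else NA_real_,
        slope = if (!is.null(f)) f$slope else NA_real_,
        slope_ci_low = if (!is.null(f)) f$slope_ci[1] else NA_real_,
        slope_ci_high = if (!is.null(f)) f$slope_ci[2] else NA_real_,
        r2 = if (!is.null(f)) f$r2 else NA_real_,
        n = if (!is.null(f)) f$n else NA_integer_,
        common_slope_p = if (!is.null(cst)) cst$p else NA_real_,
        letter = lets[i], stringsAsFactors = FALSE)
    }
  }
  # tree-level conduit tapering
  taper <- do.call(rbind, lapply(split(trunk, trunk$tree_id), function(d) {
    f <- suppressWarnings(conduit_taper(d$distance_from_top, d$d_h))
    data.frame(tree_id = d$tree_id[1], cohort = d$cohort[1],
               t_conduit = if (inherits(f, "sma_fit")) f$slope else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(taper) <- NULL
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       taper = taper)
}

.path_stage <- function(derived, leaves, alpha) {
  derived$diameter <- 2 * derived$s_r
  out_rows <- list(); contr_rows <- list(); models <- list()
  add <- function(level, cohort, model, hydro) {
    eff <- model$effects
    eff <- cbind(level = level, cohort = cohort, eff)
    out_rows[[length(out_rows) + 1L]] <<- eff
    c1 <- wald_contrast(model, c("cambial_age", "indirect"),
                        c(hydro, "indirect"))
    c2 <- wald_contrast(model, c(hydro, "direct"), c(hydro, "indirect"))
    contr_rows[[length(contr_rows) + 1L]] <<- data.frame(
      level = level, cohort = cohort,
      contrast = c(c1$description, c2$description),
      chi2 = c(c1$statistic, c2$statistic), df = 1L,
      p = c(c1$p, c2$p), stringsAsFactors = FALSE)
    models[[paste(level, cohort, sep = ".")]] <<- model
  }
  trunk <- derived[derived$disc_type == "trunk" & !is.na(derived$tcva), ]
  for (ch in unique(trunk$cohort))
    add("trunk", ch,
        fit_path(trunk[trunk$cohort == ch, ], outcome = "hwa",
                 mediator = "diameter",
                 exogenous = c("cambial_age", "tcva")), "tcva")
  br <- derived[derived$disc_type == "branch", ]
  br <- merge(br, leaves[c("branch_id", "total_leaf_area")],
              by.x = "disc_id", by.y = "branch_id")
  for (ch in unique(br$cohort))
    add("branch", ch,
        fit_path(br[br$cohort == ch, ], outcome = "swa",
                 mediator = "diameter",
                 exogenous = c("cambial_age", "total_leaf_area")),
        "total_leaf_area")
  list(effects = do.call(rbind, c(out_rows, make.row.names = FALSE)),
       contrasts = do.call(rbind, c(contr_rows, make.row.names = FALSE)),
       models = models)
}

.report_stage <- function(derived, dataset, taper, alpha) {
  trees <- dataset$trees
  trunk <- derived[derived$disc_type == "trunk", ]
  tree_means <- function(df, var, id = "tree_id")
    tapply(df[[var]], df[[id]], mean, na.rm = TRUE)
  per_tree <- data.frame(tree_id = trees$tree_id, cohort = trees$cohort,
                         stringsAsFactors = FALSE)
  add_var <- function(per_tree, vals, name) {
    per_tree[[name]] <- as.numeric(vals[per_tree$tree_id]); per_tree
  }
  per_tree <- add_var(per_tree, tree_means(trunk, "gr"), "gr")
  per_tree <- add_var(per_tree, tree_means(trunk, "d_h"), "d_h")
  per_tree <- add_var(per_tree, tree_means(trunk, "n_v"), "n_v")
  per_tree <- add_var(per_tree, tree_means(trunk, "a_v"), "a_v")
  per_tree <- add_var(per_tree, tree_means(trunk, "tcva"), "tcva")
  per_tree <- add_var(per_tree, tree_means(trunk, "f_v"), "f_v")
  tp <- stats::setNames(taper$t_conduit, taper$tree_id)
  per_tree <- add_var(per_tree, tp, "t_conduit")
  per_tree <- add_var(per_tree,
                      tree_means(dataset$leaves, "mean_leaf_area"), "a_l")
  per_tree <- add_var(per_tree,
                      tree_means(dataset$leaves, "total_leaf_area"),
                      "branch_a_l")
  gm <- gmax(dataset$stomata$stomatal_density, dataset$stomata$stomatal_size)
  per_tree <- add_var(per_tree,
                      tapply(gm, dataset$stomata$tree_id, mean), "g_max")
  traits <- setdiff(names(per_tree), c("tree_id", "cohort"))
  tab <- do.call(rbind, lapply(traits, function(v) {
    ok <- !is.na(per_tree[[v]])
    kw <- kruskal_wallis(per_tree[[v]][ok], per_tree$cohort[ok])
    lets <- .letters_from_p(kw$p, alpha)
    agg_m <- tapply(per_tree[[v]][ok], per_tree$cohort[ok], mean)
    agg_s <- tapply(per_tree[[v]][ok], per_tree$cohort[ok], stats::sd)
    do.call(rbind, lapply(seq_along(agg_m), function(i)
      data.frame(trait = v, cohort = names(agg_m)[i],
                 mean = unname(agg_m[i]), sd = unname(agg_s[i]),
                 kruskal_h = kw$statistic, kruskal_p = kw$p,
                 letter = lets[i], stringsAsFactors = FALSE)))
  }))
  rownames(tab) <- NULL
  list(trait_summary = tab, per_tree = per_tree)
}

#' Run the full heartwood-formation analysis pipeline
#'
#' Generates the two-cohort dataset, derives disc traits, and runs the
#' onset, dynamics, SMA/tapering, path-model and cohort-contrast stages.
#' Identical configuration and seed reproduce the bundle exactly.
#'
#' @param config a [run_config()].
#' @return object of class \code{report_bundle}: result tables
#'   (\code{trait_summary}, \code{onset}, \code{onset_lrt},
#'   \code{dynamics}, \code{ring}, \code{sma}, \code{taper},
#'   \code{path_effects}, \code{path_contrasts}), a \code{qualitative}
#'   sign-pattern summary, fitted objects in \code{details}, the generated
#'   \code{dataset} and \code{derived} table, and a \code{manifest} that
#'   fully determines every table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds <- .stage("simulate", generate_study(config$cohorts, config$seed))
  derived <- .stage("derive", {
    d <- disc_traits(ds$discs, ds$vessels)
    d$site <- as.integer(d$cohort == "sun_exposed")
    d$diameter <- 2 * d$s_r
    d
  })
  onset <- .stage("onset", .onset_stage(derived, config$alpha,
                                        config$gr_split))
  dyn <- .stage("dynamics", .dynamics_stage(derived, config$alpha))
  sma <- .stage("sma", .sma_stage(derived, config$cohorts, config$alpha))
  path <- .stage("path", .path_stage(derived, ds$leaves, config$alpha))
  rep_ <- .stage("report", .report_stage(derived, ds, sma$taper,
                                         config$alpha))

  ring <- dyn$ring
  pw <- dyn$power_by_cohort
  eff <- path$effects
  get_eff <- function(cohort, source, kind, col = "estimate")
    eff[eff$level == "trunk" & eff$cohort == cohort & eff$source == source &
          eff$kind == kind, col]
  qual <- data.frame(
    check = c("earlier_age_threshold_fast_growers",
              "larger_diameter_threshold_fast_growers",
              "higher_ring_rate_shaded",
              "steeper_hwa_age_power_shaded",
              "positive_indirect_age_both_cohorts",
              "direct_hydraulic_only_shaded"),
    pass = c(
      onset$thresholds$age_fast < onset$thresholds$age_slow,
      onset$thresholds$diam_sun > onset$thresholds$diam_shaded,
      ring$ring_rate[ring$cohort == "shaded"] >
        ring$ring_rate[ring$cohort == "sun_exposed"],
      pw$shaded$params[["a1"]] > pw$sun_exposed$params[["a1"]],
      get_eff("shaded", "cambial_age", "indirect") > 0 &&
        get_eff("sun_exposed", "cambial_age", "indirect") > 0,
      get_eff("shaded", "tcva", "direct", "p") < config$alpha &&
        get_eff("sun_exposed", "tcva", "direct", "p") >= config$alpha))

  manifest <- list(seed = config$seed, alpha = config$alpha,
                   gr_split = config$gr_split,
                   package_version =
                     as.character(utils::packageVersion("heartwoodkit")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   n_trees = nrow(ds$trees), n_discs = nrow(ds$discs),
                   cohorts = lapply(config$cohorts, unclass))

  bundle <- structure(
    list(trait_summary = rep_$trait_summary, onset = onset$table,
         onset_lrt = onset$lrt, dynamics = dyn$table, ring = ring,
         sma = sma$table, taper = sma$taper, path_effects = path$effects,
         path_contrasts = path$contrasts, qualitative = qual,
         manifest = manifest,
         details = list(onset = onset, dynamics = dyn, path = path,
                        per_tree = rep_$per_tree),
         dataset = ds, derived = derived),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Heartwood analysis report bundle (seed", x$manifest$seed, ")\n")
  cat(sprintf("  %d trees, %d discs; tables: %s\n", x$manifest$n_trees,
              x$manifest$n_discs,
              paste(c("trait_summary", "onset", "dynamics", "ring", "sma",
                      "taper", "path_effects", "path_contrasts"),
                    collapse = ", ")))
  cat("  qualitative sign pattern:\n")
  print(x$qualitative, row.names = FALSE)
  invisible(x)
}

.bundle_files <- c(trait_summary = "trait_summary.csv",
                   onset = "onset_results.csv",
                   onset_lrt = "onset_lrt.csv",
                   dynamics = "dynamics_results.csv",
                   ring = "ring_conversion.csv",
                   sma = "sma_results.csv",
                   taper = "conduit_taper.csv",
                   path_effects = "path_results.csv",
                   path_contrasts = "path_contrasts.csv",
                   qualitative = "qualitative_checks.csv")

#' Write the result tables of a report bundle to CSV
#'
#' Writes the frozen-schema result tables plus \code{manifest.json}. On any
#' failure, partially written files are removed.
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tryCatch({
    for (tab in names(.bundle_files)) {
      p <- file.path(dir, .bundle_files[[tab]])
      utils::write.csv(bundle[[tab]], p, row.names = FALSE,
                       fileEncoding = "UTF-8")
      written <- c(written, p)
    }
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(bundle$manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }, error = function(e) {
    unlink(written)
    stop("writing report bundle failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(written)
}
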