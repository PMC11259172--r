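#' Analysis run configuration
#'
#' One configuration drives the full gradient analysis and every robustness
#' variant. Inputs can be in-memory data frames (as produced by
#' [generate_cohort()]) or CSV paths.
#'
#' @param gazetteer Gazetteer data frame or CSV path (columns `name`,
#'   `easting`/`northing` or `lon`/`lat`, `population`, optional
#'   `area_km2`).
#' @param cohort Participant table or CSV path: `participant_id`,
#'   coordinates, one column per item, `age`, optional `weight`,
#'   `district_id`, `ethnicity_group`.
#' @param districts Optional district density table or CSV path
#'   (`district_id`, `density_per_km2`), needed for the density variant.
#' @param min_population Gazetteer threshold; main analysis 200,000.
#' @param normalization `"sqrt_population"` or `"radius"`.
#' @param exclude_city Optional city name; participants assigned to it are
#'   excluded after assignment (the London-exclusion check).
#' @param covariate_adjustment Add age and z-scored income smooths to both
#'   predictors.
#' @param use_weights Use the cohort's `weight` column as observation
#'   weights.
#' @param urbanicity_variant `"adjusted_distance"` (the main measure) or
#'   `"log_density"`.
#' @param subgroup_filter Optional `list(column =, value =)` row filter
#'   (e.g. an ethnicity subgroup).
#' @param items Items to analyze; default all eight.
#' @param estimation_max,reporting_max Range bounds on the adjusted-distance
#'   scale (0.07 / 0.05). Under radius normalization both are rescaled by
#'   the gazetteer's median sqrt(population)/radius ratio so they describe
#'   the same physical radii.
#' @param grid_n Reporting grid size (default 501).
#' @param spec [spline_spec()] for the urbanicity smooths; its range is
#'   set from `estimation_max` at run time.
#' @param codes Special response codes ([special_codes()]).
#' @param reference_cities Populations for km conversions.
#' @param seed Seed recorded in the run log (fits are deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(gazetteer, cohort, districts = NULL,
                       min_population = 200000,
                       normalization = c("sqrt_population", "radius"),
                       exclude_city = NULL,
                       covariate_adjustment = FALSE,
                       use_weights = FALSE,
                       urbanicity_variant = c("adjusted_distance",
                                              "log_density"),
                       subgroup_filter = NULL,
                       items = item_specs()$item,
                       estimation_max = 0.07, reporting_max = 0.05,
                       grid_n = 501L,
                       spec = spline_spec(),
                       codes = special_codes(),
                       reference_cities = urbangrad::reference_cities(),
                       seed = 1L) {
  normalization <- match.arg(normalization)
  urbanicity_variant <- match.arg(urbanicity_variant)
  structure(as.list(environment()), class = "run_config")
}

load_table <- function(x) {
  if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else
    as.data.frame(x)
}

#' Run the full gradient analysis
#'
#' Executes the pipeline defined by a [run_config()]: gazetteer filtering,
#' nearest-city assignment, range masks, per-item response filtering and
#' z-scoring (standardization on the estimation sample), location-scale
#' fits (Bernoulli for loneliness), predicted curves with 95% bands on the
#' reporting grid, and the optima/effect-size table. Filter counts and
#' convergence flags are collected in a run log; non-converged fits are
#' reported and the pipeline continues.
#'
#' @param config A [run_config()].
#' @return List of class `gradient_run`: `curves` (named list of
#'   `gradient_curve`), `peaks` (data frame), `assignments`, `log`,
#'   `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gaz <- load_table(config$gazetteer)
  gaz <- gazetteer(gaz, coords = gazetteer_coords(gaz))
  cohort <- load_table(config$cohort)
  run_log <- list(seed = config$seed,
                  n_cohort = nrow(cohort))

  gaz <- filter_gazetteer(gaz, config$min_population)
  run_log$n_cities <- nrow(gaz)

  if (!is.null(config$subgroup_filter)) {
    sf <- config$subgroup_filter
    keep <- cohort[[sf$column]] == sf$value
    run_log$subgroup <- c(kept = sum(keep), removed = sum(!keep))
    cohort <- cohort[keep, , drop = FALSE]
  }

  asg <- assign_nearest(cohort, gaz, normalization = config$normalization)

  if (!is.null(config$exclude_city)) {
    drop <- asg$nearest_city == config$exclude_city
    run_log$excluded_city <- c(city = config$exclude_city,
                               removed = sum(drop))
    cohort <- cohort[!drop, , drop = FALSE]
    asg <- asg[!drop, , drop = FALSE]
  }

  # scale factor so range bounds under radius normalization describe the
  # same physical radii as the sqrt-population bounds
  est_max <- config$estimation_max
  rep_max <- config$reporting_max
  if (config$normalization == "radius") {
    ratio <- stats::median(sqrt(gaz$population) / radius_from_area(gaz$area_km2))
    est_max <- est_max * ratio
    rep_max <- rep_max * ratio
    run_log$radius_scale_ratio <- ratio
  }

  if (config$urbanicity_variant == "log_density") {
    districts <- load_table(config$districts)
    ds <- log_density(cohort, districts)
    run_log$density_counts <- attr(ds, "counts")
    ok <- ds$status == "included"
    x_all <- ds$log_density
    est_lo <- stats::quantile(x_all[ok], 0.005, names = FALSE)
    est_hi <- stats::quantile(x_all[ok], 0.995, names = FALSE)
    x_mask <- ok & x_all >= est_lo & x_all <= est_hi
    x <- x_all
    grid <- seq(est_lo, est_hi, length.out = config$grid_n)
    spec <- config$spec
    spec$range <- c(est_lo, est_hi)
    est_mask <- x_mask
  } else {
    x <- asg$d
    masks <- range_masks(x, est_max, rep_max)
    est_mask <- masks$estimation
    grid <- seq(0, rep_max, length.out = config$grid_n)
    spec <- config$spec
    spec$range <- c(0, est_max)
  }
  run_log$n_estimation <- sum(est_mask)

  # covariates prepared once (age; income recoded to pounds and z-scored)
  covs_all <- NULL
  if (config$covariate_adjustment) {
    inc <- cohort$income
    inc_ok <- !is.na(inc) & inc %in% 1:5
    inc_pounds <- rep(NA_real_, nrow(cohort))
    inc_pounds[inc_ok] <- recode_income(inc[inc_ok])
    covs_all <- data.frame(age = cohort$age, income = inc_pounds)
  }

  items <- item_specs()
  items <- items[items$item %in% config$items, , drop = FALSE]
  curves <- list()
  run_log$items <- list()
  weights_all <- if (config$use_weights) {
    if (is.null(cohort$weight)) stop("use_weights = TRUE but no weight column",
                                     call. = FALSE)
    cohort$weight
  } else NULL

  for (i in seq_len(nrow(items))) {
    it <- items$item[i]
    res <- tryCatch(
      fit_item(it, items$response_type[i], cohort, x, est_mask, spec, grid,
               covs_all, weights_all, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      run_log$items[[it]] <- list(error = conditionMessage(res))
      next
    }
    curves[[it]] <- res$curve
    run_log$items[[it]] <- res$log
  }

  peaks <- peaks_table(curves, items = item_specs(),
                       cities = config$reference_cities)
  structure(list(curves = curves, peaks = peaks, assignments = asg,
                 log = run_log, config = config),
            class = "gradient_run")
}

fit_item <- function(item, response_type, cohort, x, est_mask, spec, grid,
                     covs_all, weights_all, config) {
  if (is.null(cohort[[item]])) stop("item column '", item, "' absent")
  df <- data.frame(value = cohort[[item]], x = x)
  keep0 <- est_mask & is.finite(df$x)
  df <- df[keep0, , drop = FALSE]
  covs <- if (!is.null(covs_all)) covs_all[keep0, , drop = FALSE] else NULL
  w <- if (!is.null(weights_all)) weights_all[keep0] else NULL

  filt <- filter_responses(df, item, codes = config$codes)
  counts <- attr(filt, "counts")
  sel <- rownames(df) %in% rownames(filt)
  covs <- if (!is.null(covs)) covs[sel, , drop = FALSE] else NULL
  w <- if (!is.null(w)) w[sel] else NULL

  if (response_type == "binary") {
    fit <- fit_bernoulli(filt$value, filt$x, spec = spec, weights = w)
    curve <- predict_with_bands(fit, grid)
    p_bar <- if (is.null(w)) mean(filt$value) else
      sum(w * filt$value) / sum(w)
    attr(curve, "p_marginal") <- p_bar
  } else {
    v <- filt$value
    if (response_type == "income_bands") v <- recode_income(v)
    zs <- zscore(v)
    covs_fit <- covs
    if (!is.null(covs_fit) && item == "income") covs_fit$income <- NULL
    fit <- fit_normal_locscale(zs$z, filt$x, spec = spec, weights = w,
                               covariates = covs_fit)
    curve <- predict_with_bands(fit, grid)
  }
  list(curve = curve,
       log = list(counts = counts, n_fit = fit$n,
                  converged = fit$converged, algorithm = fit$algorithm,
                  edf_mu = unname(fit$mu$edf[1]),
                  edf_sigma = if (!is.null(fit$sigma) &&
                                  is.null(fit$sigma$constant))
                    unname(fit$sigma$edf[1]) else NA_real_,
                  concurvity = fit$concurvity))
}

#' Run the robustness suite
#'
#' Re-runs the analysis under the published robustness variants: minimum
#' city population 50k/100k/150k/200k, exclusion of the largest city,
#' age+income covariate adjustment, radius normalization, participation
#' weights, and the log population-density urbanicity variant. Variant
#' failures are isolated and reported, never silently dropped.
#'
#' @param config Base [run_config()] (the main analysis).
#' @param variants Character vector selecting variants; default all that
#'   the inputs support.
#' @return List of class `robustness_suite`: `runs` (named list of
#'   `gradient_run` or error message), `comparison` (d_star and effect
#'   size per variant x item x curve kind, with failures marked).
#' @export
run_robustness_suite <- function(config,
                                 variants = c("min_pop_50k", "min_pop_100k",
                                              "min_pop_150k", "min_pop_200k",
                                              "exclude_largest",
                                              "covariates", "radius",
                                              "weights", "log_density")) {
  base <- run_analysis(config)
  gaz <- load_table(config$gazetteer)
  largest <- gaz$name[which.max(gaz$population)]
  cohort <- load_table(config$cohort)

  mk <- function(...) {
    cfg <- config
    mods <- list(...)
    for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
    cfg
  }
  defs <- list(
    min_pop_50k = mk(min_population = 50000),
    min_pop_100k = mk(min_population = 100000),
    min_pop_150k = mk(min_population = 150000),
    min_pop_200k = mk(min_population = 200000),
    exclude_largest = mk(exclude_city = largest),
    covariates = mk(covariate_adjustment = TRUE),
    radius = mk(normalization = "radius"),
    weights = mk(use_weights = TRUE),
    log_density = mk(urbanicity_variant = "log_density")
  )
  defs <- defs[intersect(variants, names(defs))]
  if (is.null(cohort$weight)) defs$weights <- NULL
  if (is.null(config$districts)) defs$log_density <- NULL

  runs <- list(base = base)
  for (nm in names(defs)) {
    runs[[nm]] <- tryCatch(run_analysis(defs[[nm]]),
                           error = function(e) conditionMessage(e))
  }

  comparison <- do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    if (!inherits(r, "gradient_run")) {
      return(data.frame(variant = nm, item = NA, curve_kind = NA,
                        d_star = NA_real_, effect_size = NA_real_,
                        status = paste("failed:", r),
                        stringsAsFactors = FALSE))
    }
    pk <- r$peaks
    data.frame(variant = nm, item = pk$item, curve_kind = pk$curve_kind,
               d_star = pk$d_star, effect_size = pk$effect_size,
               status = "ok", stringsAsFactors = FALSE)
  }))
  structure(list(runs = runs, comparison = comparison),
            class = "robustness_suite")
}

#' Write run outputs to a directory
#'
#' Emits `curves/<item>.csv`, `peaks.csv`, and `run_log.json` under `dir`;
#' for a robustness suite additionally `robustness.csv`.
#'
#' @param run A `gradient_run` or `robustness_suite`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(file.path(dir, "curves"), recursive = TRUE,
             showWarnings = FALSE)
  if (inherits(run, "robustness_suite")) {
    utils::write.csv(run$comparison, file.path(dir, "robustness.csv"),
                     row.names = FALSE)
    write_run(run$runs$base, dir)
    return(invisible(dir))
  }
  for (nm in names(run$curves)) {
    utils::write.csv(as.data.frame(run$curves[[nm]]),
                     file.path(dir, "curves", paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(run$peaks, file.path(dir, "peaks.csv"), row.names = FALSE)
  jsonlite::write_json(run$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(dir)
}
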