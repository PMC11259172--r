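#' Configuration for the synthetic cohort generator
#'
#' Describes a seeded synthetic gazetteer and cohort carrying the
#' statistical structure the gradient analysis assumes: participants
#' spatially clustered around monocentric cities of stated populations, and
#' per-item latent Gaussian outcomes whose mean and SD vary smoothly with
#' the adjusted distance d, discretized into the survey's answer formats
#' (6-point Likert scales, five income bands, a binary loneliness item).
#'
#' Truth curves use the parametric family
#' `f(d) = baseline + amplitude * exp(-((d - location) / width)^2)`; the
#' loneliness truth lives on the log-odds scale. Defaults emulate the
#' published gradient shapes: satisfaction means peak in the hinterlands
#' around d = 0.02, income rises sharply toward city centers, and income's
#' SD increases toward the centers.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param cities Gazetteer data frame (planar metres). Default: Reading
#'   (230,000), Glasgow (630,000), London (8.8 million), far apart, with
#'   areas at a common density so area is proportional to population.
#' @param n_participants Cohort size.
#' @param p_near_city Fraction placed near a city (assignment probability
#'   proportional to population, raw distance exponential); the rest are
#'   uniform over the bounding region.
#' @param decay_d_scale Mean of the exponential raw-distance draw, expressed
#'   on the adjusted scale (km per sqrt(person)); the km scale for city c is
#'   `decay_d_scale * sqrt(population_c)`.
#' @param rural_margin_km Margin added around the cities' bounding box for
#'   the uniform rural fraction.
#' @param truth Named list of per-item truth parameters; see
#'   [default_truth()].
#' @param likert_cutpoints Five ordered latent cutpoints for Likert items
#'   (left-skewed responses by default).
#' @param income_cutpoints Four ordered latent cutpoints for the five income
#'   bands.
#' @param age_mean,age_sd,female_fraction Demographics (55, 7.7, 0.57).
#' @param missing_rate Per-item missing-code rate.
#' @param dontknow_rate Do-not-know rate for meaningful life.
#' @param jobless_rate Jobless rate for job satisfaction.
#' @param weight_model `NULL` (no weights column) or `"lognormal"` for
#'   mean-one lognormal participation weights (log-SD 0.2).
#' @param confounder_strength Strength of the planted income confounding of
#'   financial satisfaction; see [plant_confounder()].
#' @param district_cell_km Grid cell size for synthetic districts used by
#'   the population-density variant.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             cities = default_cities(),
                             n_participants = 20000L,
                             p_near_city = 0.8,
                             decay_d_scale = 0.012,
                             rural_margin_km = 50,
                             truth = default_truth(),
                             likert_cutpoints = c(-1.8, -1.2, -0.6, 0, 0.9),
                             income_cutpoints = c(-1, 0, 0.8, 1.5),
                             age_mean = 55, age_sd = 7.7,
                             female_fraction = 0.57,
                             missing_rate = 0.005,
                             dontknow_rate = 0.02,
                             jobless_rate = 0.1,
                             weight_model = NULL,
                             confounder_strength = 0,
                             district_cell_km = 20) {
  cfg <- as.list(environment())
  stopifnot(all(diff(likert_cutpoints) > 0), length(likert_cutpoints) == 5L,
            all(diff(income_cutpoints) > 0), length(income_cutpoints) == 4L,
            decay_d_scale > 0, p_near_city >= 0, p_near_city <= 1)
  for (nm in names(truth)) {
    loc <- truth[[nm]]$mu["location"]
    if (!is.null(loc) && is.finite(loc) && (loc < 0 || loc > 0.05)) {
      stop("bump location for ", nm, " outside [0, 0.05]", call. = FALSE)
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_cities <- function() {
  gazetteer(data.frame(
    name = c("Reading", "Glasgow", "London"),
    easting = c(100000, 150000, 700000),
    northing = c(100000, 800000, 150000),
    population = c(230000, 630000, 8800000),
    area_km2 = c(230000, 630000, 8800000) / 5600,
    stringsAsFactors = FALSE
  ), coords = "planar")
}

bump <- function(d, pars) {
  pars["baseline"] + pars["amplitude"] *
    exp(-((d - pars["location"]) / pars["width"])^2)
}

tp <- function(baseline, amplitude, location, width) {
  c(baseline = baseline, amplitude = amplitude, location = location,
    width = width)
}

#' Default truth curves for the synthetic cohort
#'
#' Gaussian-bump mean and SD curves per item (log-odds for loneliness),
#' shaped after the published gradients: hinterland optima near d = 0.02
#' for the satisfaction items, a sharp income increase and inflated income
#' SD toward city centers, monotone job satisfaction.
#'
#' @return Named list; each element has `mu` and `sigma` parameter vectors
#'   (`logit` instead, for loneliness).
#' @export
default_truth <- function() {
  list(
    happiness = list(mu = tp(0, 0.15, 0.018, 0.015),
                     sigma = tp(1, 0, 0.02, 0.02)),
    meaningful_life = list(mu = tp(0, 0.2, 0.02, 0.01),
                           sigma = tp(1.05, -0.1, 0.025, 0.015)),
    family_satisfaction = list(mu = tp(0, 0.26, 0.02, 0.015),
                               sigma = tp(1.05, -0.1, 0.03, 0.015)),
    friendship_satisfaction = list(mu = tp(0, 0.12, 0.018, 0.015),
                                   sigma = tp(1.05, -0.12, 0.036, 0.015)),
    loneliness = list(logit = tp(-1.5, -0.35, 0.024, 0.015)),
    income = list(mu = tp(0, 0.51, 0, 0.02),
                  sigma = tp(0.9, 0.3, 0, 0.025)),
    financial_satisfaction = list(mu = tp(0, 0.12, 0.025, 0.015),
                                  sigma = tp(1.05, -0.1, 0.02, 0.015)),
    job_satisfaction = list(mu = tp(0.05, -0.08, 0, 0.03),
                            sigma = tp(1, 0, 0.02, 0.02))
  )
}

#' Evaluate a truth curve
#'
#' @param truth Truth list (from a config or [default_truth()]).
#' @param item Item name.
#' @param what `"mu"`, `"sigma"` or `"logit"`.
#' @param d Urbanicity values.
#' @return Curve values.
#' @export
truth_curve <- function(truth, item, what, d) {
  pars <- truth[[item]][[what]]
  if (is.null(pars)) stop("no ", what, " truth for ", item, call. = FALSE)
  unname(bump(d, pars))
}

#' Plant an income confounder
#'
#' Returns a config whose financial-satisfaction latent mean is shifted by
#' the (centered) income latent, while income itself already rises near
#' city centers — so adjusting for income as a covariate is testable: the
#' adjusted gradient should be closer to the clean truth than the
#' unadjusted one. Strength 0 leaves the cohort distribution unchanged.
#'
#' @param config A [synthetic_config()].
#' @param strength Confounding coefficient.
#' @return Modified config.
#' @export
plant_confounder <- function(config, strength) {
  stopifnot(is.finite(strength))
  config$confounder_strength <- strength
  config
}

#' Generate a synthetic gazetteer and cohort
#'
#' Deterministic given `config$seed` (the global RNG state is preserved).
#' Latent outcomes are drawn as `mu*(d) + sigma*(d) * N(0,1)` and
#' discretized through the configured cutpoints; loneliness is a Bernoulli
#' draw at the configured log-odds. Special codes are planted for missing
#' (all items), do-not-know (meaningful life) and jobless (job
#' satisfaction).
#'
#' @param config A [synthetic_config()].
#' @return List: `gazetteer`, `participants` (cohort table with planar home
#'   coordinates, item responses with special codes, age, sex,
#'   ethnicity_group, district_id, optional weight), `districts` (density
#'   table), `assignments` (nearest city and d, as generated), `latent`
#'   (the continuous latent outcome per Gaussian item, before
#'   discretization), and `truth` (the generating parameters).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  cities <- config$cities
  n <- config$n_participants
  codes <- special_codes()

  # --- placement
  near <- stats::runif(n) < config$p_near_city
  city_idx <- sample.int(nrow(cities), n, replace = TRUE,
                         prob = cities$population)
  scale_km <- config$decay_d_scale * sqrt(cities$population)
  raw_km <- stats::rexp(n, rate = 1) * scale_km[city_idx]
  angle <- stats::runif(n, 0, 2 * pi)
  ex <- cities$easting[city_idx] + raw_km * 1000 * cos(angle)
  ny <- cities$northing[city_idx] + raw_km * 1000 * sin(angle)
  m <- config$rural_margin_km * 1000
  bb <- c(min(cities$easting) - m, max(cities$easting) + m,
          min(cities$northing) - m, max(cities$northing) + m)
  ex[!near] <- stats::runif(sum(!near), bb[1], bb[2])
  ny[!near] <- stats::runif(sum(!near), bb[3], bb[4])

  participants <- data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    easting = ex, northing = ny,
    stringsAsFactors = FALSE
  )
  asg <- assign_nearest(participants, cities)
  d <- asg$d

  # --- demographics
  participants$age <- round(stats::rnorm(n, config$age_mean, config$age_sd), 1)
  participants$sex <- ifelse(stats::runif(n) < config$female_fraction,
                             "female", "male")
  participants$ethnicity_group <- sample(
    c("white", "black", "asian", "other"), n, replace = TRUE,
    prob = c(0.97, 0.008, 0.009, 0.013))

  # --- districts (grid cells; density decays away from centers)
  cell <- config$district_cell_km * 1000
  gx <- floor((ex - bb[1]) / cell)
  gy <- floor((ny - bb[3]) / cell)
  participants$district_id <- sprintf("D_%03d_%03d", gx, gy)
  grid_cells <- unique(data.frame(gx = gx, gy = gy))
  cx <- bb[1] + (grid_cells$gx + 0.5) * cell
  cy <- bb[3] + (grid_cells$gy + 0.5) * cell
  dens <- rep(20, nrow(grid_cells))  # rural baseline persons/km^2
  for (j in seq_len(nrow(cities))) {
    dist_km <- sqrt((cx - cities$easting[j])^2 +
                    (cy - cities$northing[j])^2) / 1000
    s <- scale_km[j]
    dens <- dens + cities$population[j] / (2 * pi * s^2) * exp(-dist_km / s)
  }
  # a few extreme low-density outliers, as real district tables have
  ol <- order(dens)[seq_len(max(1L, floor(0.002 * length(dens))))]
  dens[ol] <- dens[ol] * 1e-3
  districts <- data.frame(
    district_id = sprintf("D_%03d_%03d", grid_cells$gx, grid_cells$gy),
    density_per_km2 = dens, stringsAsFactors = FALSE)

  # --- latent outcomes and discretization
  items <- item_specs()
  latent <- data.frame(participant_id = participants$participant_id,
                       stringsAsFactors = FALSE)
  income_latent <- NULL
  for (it in items$item[items$response_type != "binary"]) {
    noise <- stats::rnorm(n)
    mu_d <- truth_curve(config$truth, it, "mu", d)
    sd_d <- truth_curve(config$truth, it, "sigma", d)
    lat <- mu_d + sd_d * noise
    if (it == "income") income_latent <- lat
    if (it == "financial_satisfaction" && config$confounder_strength != 0) {
      lat <- lat + config$confounder_strength *
        (income_latent - mean(income_latent))
    }
    latent[[it]] <- lat
  }
  lon_logit <- truth_curve(config$truth, "loneliness", "logit", d)
  loneliness <- stats::rbinom(n, 1L, stats::plogis(lon_logit))

  for (i in seq_len(nrow(items))) {
    it <- items$item[i]
    v <- switch(items$response_type[i],
      likert6 = as.integer(cut(latent[[it]],
                               c(-Inf, config$likert_cutpoints, Inf),
                               labels = FALSE)),
      income_bands = as.integer(cut(latent[[it]],
                                    c(-Inf, config$income_cutpoints, Inf),
                                    labels = FALSE)),
      binary = loneliness
    )
    miss <- stats::runif(n) < config$missing_rate
    v[miss] <- codes$missing
    if (it == "meaningful_life") {
      dk <- !miss & stats::runif(n) < config$dontknow_rate
      v[dk] <- codes$dontknow
    }
    if (it == "job_satisfaction") {
      jl <- !miss & stats::runif(n) < config$jobless_rate
      v[jl] <- codes$jobless
    }
    participants[[it]] <- v
  }

  if (identical(config$weight_model, "lognormal")) {
    w <- exp(stats::rnorm(n, 0, 0.2))
    participants$weight <- w / mean(w)
  }

  list(gazetteer = cities, participants = participants,
       districts = districts, assignments = asg, latent = latent,
       truth = config$truth, config = config)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `gazetteer.csv`, `cohort.csv`, `districts.csv` and `truth.json`
#' under `dir`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$gazetteer, file.path(dir, "gazetteer.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$districts, file.path(dir, "districts.csv"),
                   row.names = FALSE)
  truth_list <- lapply(cohort$truth, function(it) lapply(it, as.list))
  jsonlite::write_json(truth_list, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
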