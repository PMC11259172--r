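#' Build or validate a city gazetteer
#'
#' A gazetteer is a data frame with one monocentric entry per city: a unique
#' `name`, center coordinates (either `lon`/`lat` degrees or
#' `easting`/`northing` metres), a positive `population`, and optionally a
#' positive `area_km2` for the radius-normalization variant.
#'
#' @param cities A data frame with the columns above.
#' @param coords `"planar"` (easting/northing metres) or `"lonlat"` (degrees).
#' @return The validated data frame, with the coordinate system recorded in
#'   attribute `"coords"`.
#' @export
gazetteer <- function(cities, coords = c("planar", "lonlat")) {
  coords <- match.arg(coords)
  cities <- as.data.frame(cities)
  need <- c("name", coord_cols(coords), "population")
  miss <- setdiff(need, names(cities))
  if (length(miss)) {
    stop("gazetteer lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cities$name)) {
    stop("city names must be unique within a gazetteer", call. = FALSE)
  }
  if (any(cities$population <= 0)) stop("city populations must be positive",
                                        call. = FALSE)
  if (!is.null(cities$area_km2) &&
      any(!is.na(cities$area_km2) & cities$area_km2 <= 0)) {
    stop("city areas must be positive where present", call. = FALSE)
  }
  attr(cities, "coords") <- coords
  cities
}

coord_cols <- function(coords) {
  if (coords == "planar") c("easting", "northing") else c("lon", "lat")
}

gazetteer_coords <- function(cities, default = "planar") {
  cs <- attr(cities, "coords")
  if (is.null(cs)) {
    cs <- if (all(c("lon", "lat") %in% names(cities))) "lonlat" else default
  }
  cs
}

#' Restrict a gazetteer to cities above a minimum population
#'
#' @param cities Gazetteer data frame.
#' @param min_population Inclusive lower population bound (the main analysis
#'   default is 200,000; robustness runs use 50k/100k/150k/200k).
#' @return The subset, original order preserved.
#' @export
filter_gazetteer <- function(cities, min_population) {
  if (!is.finite(min_population) || min_population <= 0) {
    stop("min_population must be positive", call. = FALSE)
  }
  keep <- cities$population >= min_population
  if (!any(keep)) {
    stop("no city meets min_population = ", min_population,
         "; analysis cannot proceed", call. = FALSE)
  }
  out <- cities[keep, , drop = FALSE]
  attr(out, "coords") <- attr(cities, "coords")
  out
}

#' Assign each participant to its nearest city on the adjusted scale
#'
#' Computes, for every participant, the distance to every city center,
#' normalizes each by the city's size (square root of population, or
#' equivalent-disc radius in the robustness variant), and retains the lowest
#' value. Assignment therefore happens on the adjusted scale: someone in the
#' center of Reading, 55 km west of London, is assigned to Reading (d = 0),
#' not London. Ties are broken by lexicographic city name.
#'
#' @param participants Data frame with `participant_id` plus the coordinate
#'   columns matching the gazetteer (`easting`/`northing` or `lon`/`lat`).
#' @param cities Gazetteer data frame (see [gazetteer()]).
#' @param normalization `"sqrt_population"` (the main measure, km per
#'   sqrt(person)) or `"radius"` (dimensionless multiples of the city
#'   radius; requires `area_km2`).
#' @param coords Coordinate system; defaults to the gazetteer's tag.
#' @return Data frame: `participant_id`, `nearest_city`, `raw_km` (distance
#'   to the assigned center) and `d` (its normalized value).
#' @export
assign_nearest <- function(participants, cities,
                           normalization = c("sqrt_population", "radius"),
                           coords = NULL) {
  normalization <- match.arg(normalization)
  if (nrow(cities) == 0L) stop("empty gazetteer", call. = FALSE)
  if (is.null(coords)) coords <- gazetteer_coords(cities)
  cc <- coord_cols(coords)
  if (!all(cc %in% names(participants))) {
    stop("participants lack coordinate column(s) ", paste(cc, collapse = "/"),
         " for the ", coords, " system", call. = FALSE)
  }

  divisor <- switch(normalization,
    sqrt_population = sqrt(cities$population),
    radius = {
      if (is.null(cities$area_km2) || anyNA(cities$area_km2)) {
        stop("radius normalization needs area_km2 for every city",
             call. = FALSE)
      }
      radius_from_area(cities$area_km2)
    }
  )

  pm <- as.matrix(participants[, cc])
  cm <- as.matrix(cities[, cc])
  n <- nrow(pm); m <- nrow(cm)

  # n x m raw-km matrix, column per city
  raw <- if (coords == "planar") {
    dx <- outer(pm[, 1], cm[, 1], "-")
    dy <- outer(pm[, 2], cm[, 2], "-")
    sqrt(dx^2 + dy^2) / 1000
  } else {
    check_lonlat(pm); check_lonlat(cm)
    vapply(seq_len(m), function(j) {
      great_circle_km(pm, matrix(cm[j, ], n, 2, byrow = TRUE))
    }, numeric(n))
  }
  raw <- matrix(raw, nrow = n)
  adj <- sweep(raw, 2L, divisor, "/")

  # lexicographic tie-break: scan cities in name order, strict improvement
  ord <- order(cities$name)
  best <- rep.int(ord[1L], n)
  best_d <- adj[, ord[1L]]
  for (j in ord[-1L]) {
    upd <- adj[, j] < best_d
    best[upd] <- j
    best_d[upd] <- adj[upd, j]
  }

  data.frame(
    participant_id = participants$participant_id,
    nearest_city = cities$name[best],
    raw_km = raw[cbind(seq_len(n), best)],
    d = best_d,
    stringsAsFactors = FALSE
  )
}

#' Log population density urbanicity variant
#'
#' Maps participants to district population densities, log-transforms them,
#' and flags low-density outliers below a quantile cutoff (they are marked
#' excluded, never silently dropped). Participants whose district is missing
#' from the table are reported as missing.
#'
#' @param participants Data frame with `participant_id` and `district_id`.
#' @param districts Data frame with `district_id`, `density_per_km2` (> 0).
#' @param outlier_quantile Lower quantile of log-density below which a
#'   participant is excluded as a low-density outlier. Default 0.001 (0.1%).
#' @return Data frame: `participant_id`, `log_density`, and `status` in
#'   `included` / `excluded_outlier` / `missing_district`, with a `counts`
#'   attribute summarizing the three groups.
#' @export
log_density <- function(participants, districts, outlier_quantile = 0.001) {
  if (is.null(participants$district_id)) {
    stop("participants need a district_id column", call. = FALSE)
  }
  if (any(districts$density_per_km2 <= 0, na.rm = TRUE)) {
    stop("densities must be positive", call. = FALSE)
  }
  idx <- match(participants$district_id, districts$district_id)
  ld <- log(districts$density_per_km2[idx])
  status <- rep("included", length(ld))
  status[is.na(idx)] <- "missing_district"
  cut <- stats::quantile(ld[!is.na(ld)], probs = outlier_quantile,
                         names = FALSE, type = 7)
  status[!is.na(ld) & ld < cut] <- "excluded_outlier"
  out <- data.frame(
    participant_id = participants$participant_id,
    log_density = ld,
    status = status,
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- table(factor(
    status, levels = c("included", "excluded_outlier", "missing_district")))
  attr(out, "cutoff_log_density") <- cut
  out
}
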