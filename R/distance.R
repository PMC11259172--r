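#' Great-circle distance in kilometres
#'
#' Haversine distance between two points given in geographic degrees, on a
#' sphere with the mean Earth radius (6371.0088 km).
#'
#' @param p,q Numeric length-2 vectors `c(lon, lat)` in degrees, or two-column
#'   matrices of such points (recycled row-wise).
#' @param radius_km Sphere radius in km. Default is the IUGG mean radius.
#' @return Nonnegative distance(s) in km.
#' @examples
#' great_circle_km(c(0, 0), c(1, 0))  # one degree of longitude on the equator
#' @export
great_circle_km <- function(p, q, radius_km = 6371.0088) {
  p <- coord_matrix(p)
  q <- coord_matrix(q)
  check_lonlat(p)
  check_lonlat(q)
  as.vector(geosphere::distHaversine(p, q, r = radius_km * 1000)) / 1000
}

#' Planar (Euclidean) distance in kilometres
#'
#' For coordinates already on a planar national grid in metres
#' (e.g. easting/northing).
#'
#' @param p,q Numeric length-2 vectors `c(easting, northing)` in metres, or
#'   two-column matrices.
#' @return Nonnegative distance(s) in km.
#' @export
planar_km <- function(p, q) {
  p <- coord_matrix(p)
  q <- coord_matrix(q)
  sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2) / 1000
}

coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 2L) stop("a coordinate is a length-2 vector", call. = FALSE)
    x <- matrix(x, ncol = 2L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("coordinates need exactly two columns", call. = FALSE)
  if (!all(is.finite(x))) stop("coordinates must be finite", call. = FALSE)
  x
}

check_lonlat <- function(m) {
  if (any(m[, 2] < -90 | m[, 2] > 90)) {
    stop("invalid coordinate: latitude outside [-90, 90]", call. = FALSE)
  }
  invisible(m)
}

#' Size-adjusted distance
#'
#' The urbanicity score: raw distance to a city center divided by the square
#' root of the city's population, in km per sqrt(person). Zero at city
#' centers, increasing toward rural areas; large cities stretch the gradient
#' (55 km west of London is still "near" London in adjusted terms).
#'
#' @param raw_km Nonnegative raw distance(s), km.
#' @param population Positive city population count.
#' @return `raw_km / sqrt(population)`.
#' @export
adjusted_distance <- function(raw_km, population) {
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be positive", call. = FALSE)
  }
  if (any(raw_km < 0)) stop("raw_km must be nonnegative", call. = FALSE)
  raw_km / sqrt(population)
}

#' Equivalent-disc radius of a city
#'
#' Radius of a disc with the city's area, used as the divisor in the
#' radius-normalization robustness variant.
#'
#' @param area_km2 Positive area in km^2.
#' @return Radius in km, `sqrt(area / pi)`.
#' @export
radius_from_area <- function(area_km2) {
  if (any(!is.finite(area_km2)) || any(area_km2 <= 0)) {
    stop("area must be positive", call. = FALSE)
  }
  sqrt(area_km2 / pi)
}
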