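#' Locate the interior extremum of a gradient curve
#'
#' Method of differences on a dense grid: the optimum is the grid point
#' where the first differences change sign in the requested sense. A curve
#' that is monotone over the grid, or whose extreme value sits on the
#' boundary, has no interior optimum and returns `NA` (the happiness,
#' income and job-satisfaction rows of the results table).
#'
#' @param curve A `gradient_curve` or data frame with column `d`.
#' @param sense `"max"` (highest average) or `"min"` (least variation).
#' @param value_col Which column to scan; default `"mu_hat"`.
#' @return List with `d_star` (or `NA`), `kind`
#'   (`"maximum"`/`"minimum"`/`"none"`), and `value` at the optimum.
#' @export
find_extremum <- function(curve, sense = c("max", "min"),
                          value_col = "mu_hat") {
  sense <- match.arg(sense)
  d <- curve$d
  v <- curve[[value_col]]
  if (length(d) < 200L) {
    stop("grid too coarse: need at least 200 points for the method of ",
         "differences", call. = FALSE)
  }
  i <- if (sense == "max") which.max(v) else which.min(v)
  interior <- i > 1L && i < length(v)
  # require an actual sign change of the first differences at the optimum
  if (interior) {
    dv <- diff(v)
    sign_ok <- if (sense == "max") {
      dv[i - 1L] > 0 && dv[i] < 0
    } else {
      dv[i - 1L] < 0 && dv[i] > 0
    }
    interior <- interior && sign_ok
  }
  if (!interior) {
    return(list(d_star = NA_real_, kind = "none", value = NA_real_))
  }
  list(d_star = d[i], kind = if (sense == "max") "maximum" else "minimum",
       value = v[i])
}

#' Effect size of a gradient in SD units
#'
#' Absolute difference in the fitted z-scored outcome between the city
#' center (`d = 0`, the first grid point) and the optimal distance. When no
#' interior optimum exists the curve's full swing over the reporting range
#' (maximum minus minimum) is reported instead, as for income and job
#' satisfaction.
#'
#' @param curve A `gradient_curve`.
#' @param d_star Optimal distance, or `NA` for none.
#' @param value_col Column holding the fitted curve.
#' @return Nonnegative effect size.
#' @export
effect_size <- function(curve, d_star, value_col = "mu_hat") {
  v <- curve[[value_col]]
  if (is.na(d_star)) return(max(v) - min(v))
  i <- which.min(abs(curve$d - d_star))
  abs(v[1L] - v[i])
}

#' Convert an optimal distance to physical kilometres
#'
#' Optimal distances are in km per sqrt(person); for a reference city of
#' population N the physical radius is `d_star * sqrt(N)`, rounded half-up
#' to whole km for table-style reporting.
#'
#' @param d_star Optimal distance(s) (km/sqrt(person)).
#' @param population Reference city population.
#' @param digits `NULL` rounds half-up to integer km; otherwise the raw
#'   value is returned.
#' @return Kilometres.
#' @export
to_km <- function(d_star, population, digits = NULL) {
  stopifnot(all(population > 0), all(is.na(d_star) | d_star >= 0))
  km <- d_star * sqrt(population)
  if (is.null(digits)) floor(km + 0.5) else km
}

#' Default reference cities for km conversion
#'
#' Three real cities spanning the population range: Reading (230,000),
#' Glasgow (630,000) and London (8.8 million).
#'
#' @return Named vector of populations.
#' @export
reference_cities <- function() {
  c(Reading = 230000, Glasgow = 630000, London = 8800000)
}

#' Summarize optima for a set of fitted curves
#'
#' Builds a table of optimal distances, effect sizes, and per-reference-city
#' km conversions for the mean and SD curve of each item.
#'
#' @param curves Named list of `gradient_curve` objects (one per item).
#' @param items Item catalogue (see [item_specs()]), used for the healthy
#'   direction of each mean curve.
#' @param cities Named vector of reference-city populations.
#' @return Data frame with one row per item and curve kind.
#' @export
peaks_table <- function(curves, items = item_specs(),
                        cities = reference_cities()) {
  rows <- list()
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    spec_row <- items[items$item == nm, ]
    healthy_low <- nrow(spec_row) && spec_row$healthy_direction == "lower"
    fam <- attr(cv, "family")
    # mean curve: optimum is the healthiest point (max, or min for
    # lower-is-healthy items like loneliness)
    ex <- find_extremum(cv, sense = if (healthy_low) "min" else "max",
                        value_col = "mu_hat")
    es <- effect_size(cv, ex$d_star, "mu_hat")
    if (identical(fam, "bernoulli")) {
      # express the probability change in SD units of the binary outcome
      p_bar <- attr(cv, "p_marginal")
      if (!is.null(p_bar)) es <- es / sqrt(p_bar * (1 - p_bar))
    }
    rows[[length(rows) + 1L]] <- peak_row(nm, "mean", ex, es, cities)
    # SD curve: optimum is always the least variation, omitted for the
    # Bernoulli family whose variance is tied to its mean
    if (!identical(fam, "bernoulli")) {
      ex_s <- find_extremum(cv, sense = "min", value_col = "sigma_hat")
      es_s <- effect_size(cv, ex_s$d_star, "sigma_hat")
      rows[[length(rows) + 1L]] <- peak_row(nm, "sd", ex_s, es_s, cities)
    }
  }
  do.call(rbind, rows)
}

peak_row <- function(item, kind, ex, es, cities) {
  km <- if (is.na(ex$d_star)) rep(NA_real_, length(cities)) else
    to_km(ex$d_star, cities)
  out <- data.frame(item = item, curve_kind = kind, d_star = ex$d_star,
                    extremum_kind = ex$kind, effect_size = es,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cities)) {
    out[[paste0("km_", names(cities)[i])]] <- km[i]
  }
  out
}

#' Default reporting grid
#'
#' 501 equally spaced urbanicity values on the reporting range [0, 0.05]
#' (resolution 1e-4).
#'
#' @param reporting_max Upper bound, default 0.05.
#' @param n Number of grid points, default 501.
#' @return Numeric vector.
#' @export
reporting_grid <- function(reporting_max = 0.05, n = 501L) {
  seq(0, reporting_max, length.out = n)
}
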