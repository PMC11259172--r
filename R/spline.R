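#' Penalized B-spline smooth specification
#'
#' Describes one P-spline smooth: a B-spline basis of given degree on
#' equally spaced knots extended beyond the data range (so the difference
#' penalty's null space contains exactly the polynomials it should), a
#' difference penalty of given order, and a cap on the effective degrees of
#' freedom. The default mirrors the main analysis: cubic basis, 20 interior
#' knots, second-order penalty, on the urbanicity estimation range
#' [0, 0.07], with the smooth constrained to at most 3 degrees of freedom
#' beyond its constant-and-linear baseline. `max_edf` is expressed as a cap
#' on the smoother's total hat-matrix trace, so that constraint is
#' `max_edf = 5` (the trace retains the 2-dimensional penalty null space
#' however hard the penalty shrinks).
#'
#' @param degree Basis polynomial degree (>= 1).
#' @param n_interior_knots Number of interior knots (equally spaced).
#' @param penalty_order Difference-penalty order (>= 1).
#' @param max_edf Cap on the smooth's effective degrees of freedom (trace of
#'   its hat-matrix block); must be at least `penalty_order`, otherwise the
#'   target is unreachable. `Inf` leaves the smoothness choice entirely to
#'   generalized cross-validation.
#' @param range Numeric length-2 evaluation range; no silent extrapolation.
#' @return List of class `spline_spec`.
#' @export
spline_spec <- function(degree = 3L, n_interior_knots = 20L,
                        penalty_order = 2L, max_edf = 5,
                        range = c(0, 0.07)) {
  stopifnot(degree >= 1, penalty_order >= 1, n_interior_knots >= 0,
            length(range) == 2L, range[2] > range[1])
  if (max_edf < penalty_order) {
    stop("max_edf below the penalty order is unreachable", call. = FALSE)
  }
  structure(
    list(degree = as.integer(degree),
         n_interior_knots = as.integer(n_interior_knots),
         penalty_order = as.integer(penalty_order),
         max_edf = max_edf, range = as.numeric(range)),
    class = "spline_spec"
  )
}

n_basis <- function(spec) spec$n_interior_knots + spec$degree + 1L

spline_knots <- function(spec) {
  a <- spec$range[1]; b <- spec$range[2]
  k <- spec$n_interior_knots + 1L
  idx <- (-spec$degree):(k + spec$degree)
  kn <- a + (b - a) * idx / k
  kn[idx == 0L] <- a  # pin the boundary knots exactly
  kn[idx == k] <- b
  kn
}

#' Evaluate a B-spline basis
#'
#' Rows form a partition of unity over the spec's range; evaluation outside
#' the range is an error (no silent extrapolation). Column count is
#' `n_interior_knots + degree + 1`.
#'
#' @param x Evaluation points within `spec$range`.
#' @param spec A [spline_spec()].
#' @return `length(x)` by `n_basis` matrix.
#' @export
build_basis <- function(x, spec) {
  if (any(!is.finite(x))) stop("basis evaluation points must be finite",
                               call. = FALSE)
  if (any(x < spec$range[1] | x > spec$range[2])) {
    stop("extrapolation: points outside the spline range [",
         spec$range[1], ", ", spec$range[2], "]", call. = FALSE)
  }
  splines::splineDesign(spline_knots(spec), x, ord = spec$degree + 1L,
                        outer.ok = FALSE)
}

#' Difference penalty matrix
#'
#' `t(D) %*% D` for the order-`order` difference operator `D` on coefficient
#' vectors: positive semidefinite with rank `n_columns - order`, null space
#' the polynomials of degree `< order` in the coefficient index (which, on
#' the equally spaced knot grid, are exactly polynomial functions of x).
#'
#' @param n_columns Basis dimension.
#' @param order Difference order, `< n_columns`.
#' @return `n_columns` square matrix.
#' @export
penalty_matrix <- function(n_columns, order) {
  if (order >= n_columns) {
    stop("penalty order must be smaller than the number of columns",
         call. = FALSE)
  }
  D <- diff(diag(n_columns), differences = order)
  crossprod(D)
}

#' Effective degrees of freedom of a penalized smoother
#'
#' Trace of the hat matrix `X (X'WX + lambda P)^{-1} X'W`: `ncol(X)` at
#' `lambda = 0`, decreasing to the penalty null-space dimension as
#' `lambda` grows.
#'
#' @param lambda Nonnegative penalty weight.
#' @param X Design matrix.
#' @param penalty Penalty matrix.
#' @param w Optional observation weights.
#' @return The edf (a scalar).
#' @export
smoother_edf <- function(lambda, X, penalty, w = NULL) {
  if (is.null(w)) w <- rep.int(1, nrow(X))
  A <- crossprod(X, X * w)
  sum(diag(solve(A + lambda * penalty, A)))
}

#' Calibrate the penalty weight to a target edf
#'
#' Finds `lambda` such that the trace of the penalized smoother's hat matrix
#' `X (X'WX + lambda P)^{-1} X'W` equals `target_edf` (within 0.01), using
#' bisection on log-lambda; the trace is monotone decreasing in lambda.
#'
#' @param target_edf Desired effective degrees of freedom, strictly between
#'   the penalty null-space dimension and `ncol(X)`.
#' @param X Design (basis) matrix.
#' @param penalty Penalty matrix from [penalty_matrix()].
#' @param w Optional observation weights (default 1).
#' @return The calibrated nonnegative `lambda`.
#' @export
calibrate_lambda <- function(target_edf, X, penalty, w = NULL) {
  if (is.null(w)) w <- rep.int(1, nrow(X))
  A <- crossprod(X, X * w)
  null_dim <- ncol(X) - qr(penalty)$rank
  if (target_edf >= ncol(X) + 1e-8 || target_edf <= null_dim - 1e-8) {
    stop("target_edf ", target_edf, " unreachable: must lie in (",
         null_dim, ", ", ncol(X), ")", call. = FALSE)
  }
  edf_of <- function(lambda) {
    sum(diag(solve(A + lambda * penalty, A)))
  }
  if (target_edf >= ncol(X) - 0.01) return(0)
  lam_ref <- sum(diag(A)) / max(sum(diag(penalty)), 1e-300)
  lo <- lam_ref * 1e-10; hi <- lam_ref * 1e12
  # expand until bracketing
  while (edf_of(lo) < target_edf && lo > lam_ref * 1e-20) lo <- lo / 100
  while (edf_of(hi) > target_edf && hi < lam_ref * 1e20) hi <- hi * 100
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    e <- edf_of(mid)
    if (abs(e - target_edf) < 0.005) return(mid)
    if (e > target_edf) lo <- mid else hi <- mid
  }
  mid
}
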