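#' Control parameters for location-scale fitting
#'
#' @param tol Relative penalized-deviance convergence tolerance.
#' @param max_rs_iter Maximum outer cycles of the alternating
#'   (Rigby-Stasinopoulos-type) algorithm per attempt.
#' @param n_attempts Attempts of the alternating algorithm: one cold start
#'   plus jittered restarts.
#' @param cg_iter Maximum iterations of the simultaneous (Cole-Green-type,
#'   full cross-derivative) fallback.
#' @param jitter_sd SD of the coefficient jitter applied at each restart.
#' @param jitter_seed Seed for the restart jitter (the global RNG state is
#'   preserved).
#' @param freeze_after Outer cycle after which the GCV-selected smoothing
#'   parameters are frozen (the recorded deviance trace starts there, and is
#'   nonincreasing from that point).
#' @return List of class `locscale_control`.
#' @export
locscale_control <- function(tol = 1e-6, max_rs_iter = 40L, n_attempts = 5L,
                             cg_iter = 60L, jitter_sd = 0.1,
                             jitter_seed = 421L, freeze_after = 2L) {
  list(tol = tol, max_rs_iter = as.integer(max_rs_iter),
       n_attempts = as.integer(n_attempts), cg_iter = as.integer(cg_iter),
       jitter_sd = jitter_sd, jitter_seed = as.integer(jitter_seed),
       freeze_after = as.integer(freeze_after))
}

# -2 * gaussian loglik (up to constants) plus penalties
normal_pdev <- function(y, w, eta_mu, eta_s, pen_mu, pen_sigma) {
  r <- y - eta_mu
  sum(w * (2 * eta_s + r^2 * exp(-2 * eta_s))) + pen_mu + pen_sigma
}

build_mu_terms <- function(d, spec, covariates, cov_spec) {
  terms <- list(smooth_term(d, spec, "urbanicity"))
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      x <- covariates[[nm]]
      sp <- cov_spec
      sp$range <- range(x) + c(-1e-9, 1e-9) * max(1, abs(range(x)))
      terms <- c(terms, list(smooth_term(x, sp, nm, center = TRUE)))
    }
  }
  terms
}

# concurvity of each covariate with the urbanicity smooth: R^2 of the
# covariate regressed on the urbanicity basis.
concurvity_diag <- function(d_basis, covariates) {
  if (is.null(covariates)) return(NULL)
  vapply(covariates, function(x) {
    f <- stats::lm.fit(d_basis, x)
    1 - sum(f$residuals^2) / sum((x - mean(x))^2)
  }, numeric(1))
}

#' Fit a normal location-scale gradient model
#'
#' Models an outcome as `y = mu(d) + sigma(d) * e`, `e ~ N(0,1)`, with both
#' the mean and the log-SD smooth penalized B-spline functions of the
#' urbanicity score `d`. Smoothing parameters are chosen by generalized
#' cross-validation on each working model and recalibrated so no smooth
#' exceeds its `max_edf` cap (3 by default, matching the analysis design of
#' constraining maximum degrees of freedom). Fitting alternates an exact
#' penalized weighted least-squares update for the mean (working weights
#' `w/sigma^2`) with a penalized Fisher-scoring step for the log-SD driven
#' by squared standardized residuals, with step-halving so the penalized
#' deviance never increases across recorded iterations. Up to
#' `control$n_attempts` starts are made (cold start plus jittered restarts);
#' if none converges, a simultaneous Newton update with observed
#' cross-derivatives runs for up to `control$cg_iter` iterations. A fit that
#' still fails is returned flagged (`converged = FALSE`), never silently.
#'
#' @param y Numeric outcome (typically a z-scored item).
#' @param d Urbanicity values, same length, inside `spec$range`.
#' @param spec [spline_spec()] for the urbanicity smooth of the mean.
#' @param weights Optional nonnegative observation weights (participation
#'   weights); `NULL` means unweighted, and weights of all one reproduce the
#'   unweighted fit exactly.
#' @param sigma_spec [spline_spec()] for the log-SD smooth, `"constant"` for
#'   a scalar SD, or `NULL` to reuse `spec`.
#' @param covariates Optional data frame of numeric covariates (e.g. age,
#'   z-scored income) entering both the mean and log-SD predictors as
#'   centered smooths whose edf is left to GCV (uncapped).
#' @param cov_spec [spline_spec()] template for covariate smooths.
#' @param lambda_mu,lambda_sigma Optional fixed smoothing parameters for the
#'   urbanicity smooths (bypass GCV; used for oracle comparisons).
#' @param control [locscale_control()].
#' @return Object of class `locscale_fit`.
#' @export
fit_normal_locscale <- function(y, d, spec = spline_spec(), weights = NULL,
                                sigma_spec = NULL, covariates = NULL,
                                cov_spec = spline_spec(n_interior_knots = 10L,
                                                       max_edf = Inf,
                                                       range = c(0, 1)),
                                lambda_mu = NULL, lambda_sigma = NULL,
                                control = locscale_control()) {
  n <- length(y)
  stopifnot(length(d) == n)
  if (is.null(weights)) weights <- rep.int(1, n)
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- stats::complete.cases(covariates) & is.finite(y) & is.finite(d)
    n_dropped <- sum(!ok)
    if (n_dropped) {
      message(n_dropped, " rows dropped for missing covariate values")
      y <- y[ok]; d <- d[ok]; weights <- weights[ok]
      covariates <- covariates[ok, , drop = FALSE]
      n <- length(y)
    }
  } else n_dropped <- 0L

  sigma_constant <- identical(sigma_spec, "constant")
  if (is.null(sigma_spec) || sigma_constant) sspec <- spec else sspec <- sigma_spec

  mu_terms <- build_mu_terms(d, spec, covariates, cov_spec)
  sig_terms <- if (sigma_constant) NULL else
    build_mu_terms(d, sspec, covariates, cov_spec)
  p_mu <- sum(vapply(mu_terms, function(t) ncol(t$X), integer(1)))
  if (n < 10 * p_mu) {
    warning("fewer than 10 observations per basis column; fit may be unstable")
  }

  lam_mu_fixed <- if (!is.null(lambda_mu))
    c(lambda_mu, rep(NA_real_, length(mu_terms) - 1L)) else NULL
  lam_sig_fixed <- if (!is.null(lambda_sigma) && !sigma_constant)
    c(lambda_sigma, rep(NA_real_, length(sig_terms) - 1L)) else NULL

  sw <- sum(weights)
  wmean <- sum(weights * y) / sw
  eta_s0 <- 0.5 * log(max(sum(weights * (y - wmean)^2) / sw, 1e-12))

  run_rs <- function(eta_mu, eta_s, jitter = 0) {
    lam_mu <- lam_mu_fixed
    lam_sig <- lam_sig_fixed
    mu_fit <- NULL; sig_fit <- NULL
    pdev_trace <- numeric(0)
    pdev_old <- Inf
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(control$max_rs_iter)) {
      iters <- it
      frozen <- it > control$freeze_after
      # --- mean update (exact penalized WLS given sigma)
      wmu <- weights * exp(-2 * eta_s)
      mu_fit <- pwls_fit(mu_terms, y, wmu,
                         lambdas = if (frozen) mu_fit$lambdas else lam_mu)
      eta_mu <- mu_fit$eta
      if (jitter > 0 && it == 1L) {
        bj <- mu_fit$beta + stats::rnorm(length(mu_fit$beta), sd = jitter)
        eta_mu <- as.vector(mu_fit$X %*% bj)
        mu_fit$beta <- bj
        mu_fit$eta <- eta_mu
        mu_fit$penalty_quadform <- penalty_value(mu_terms, mu_fit$lambdas, bj)
      }
      r <- y - eta_mu
      # --- scale update
      if (sigma_constant) {
        eta_s_new <- rep(0.5 * log(max(sum(weights * r^2) / sw, 1e-12)), n)
        pen_sig <- 0
        sig_fit <- NULL
        eta_s <- eta_s_new
      } else {
        z <- eta_s + 0.5 * (r^2 * exp(-2 * eta_s) - 1)
        ws <- 2 * weights
        sig_new <- pwls_fit(sig_terms, z, ws,
                            lambdas = if (frozen) sig_fit$lambdas else lam_sig)
        # step-halving on the penalized deviance
        pen_mu <- mu_fit$penalty_quadform
        base_pdev <- normal_pdev(y, weights, eta_mu, eta_s, pen_mu,
                                 if (is.null(sig_fit)) 0 else
                                   penalty_value(sig_terms, sig_new$lambdas,
                                                 sig_fit$beta))
        step <- 1
        repeat {
          beta_try <- if (is.null(sig_fit)) sig_new$beta else
            (1 - step) * sig_fit$beta + step * sig_new$beta
          eta_try <- as.vector(sig_new$X %*% beta_try)
          pd_try <- normal_pdev(y, weights, eta_mu, eta_try, pen_mu,
                                penalty_value(sig_terms, sig_new$lambdas,
                                              beta_try))
          if (pd_try <= base_pdev + 1e-10 || step < 1e-4 ||
              is.null(sig_fit)) {
            sig_new$beta <- beta_try
            sig_new$eta <- eta_try
            sig_new$penalty_quadform <- penalty_value(
              sig_terms, sig_new$lambdas, beta_try)
            break
          }
          step <- step / 2
        }
        sig_fit <- sig_new
        eta_s <- sig_fit$eta
        pen_sig <- sig_fit$penalty_quadform
      }
      pdev <- normal_pdev(y, weights, eta_mu, eta_s,
                          mu_fit$penalty_quadform, pen_sig)
      if (frozen) pdev_trace <- c(pdev_trace, pdev)
      if (frozen && is.finite(pdev_old) &&
          abs(pdev - pdev_old) / (abs(pdev_old) + 0.1) < control$tol) {
        converged <- TRUE
        break
      }
      pdev_old <- pdev
    }
    list(mu_fit = mu_fit, sig_fit = sig_fit, eta_mu = eta_mu, eta_s = eta_s,
         pdev = pdev, pdev_trace = pdev_trace, converged = converged,
         iterations = iters)
  }

  # --- attempts: cold start + jittered restarts
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(control$jitter_seed)

  best <- NULL
  total_iter <- 0L
  algorithm <- "RS"
  for (attempt in seq_len(control$n_attempts)) {
    res <- run_rs(rep(wmean, n), rep(eta_s0, n),
                  jitter = if (attempt > 1L) control$jitter_sd else 0)
    total_iter <- total_iter + res$iterations
    if (is.null(best) || res$pdev < best$pdev || res$converged) best <- res
    if (res$converged) break
  }

  if (!best$converged && !sigma_constant) {
    cg <- run_cg(y, weights, mu_terms, sig_terms, best, control)
    total_iter <- total_iter + cg$iterations
    if (cg$pdev <= best$pdev + 1e-10) {
      best <- cg
      algorithm <- "CG"
    }
  }

  # --- final bookkeeping at the converged working weights
  eta_s <- best$eta_s
  wmu <- weights * exp(-2 * eta_s)
  mu_final <- pwls_fit(mu_terms, y, wmu, lambdas = best$mu_fit$lambdas)
  sig_final <- best$sig_fit
  if (!sigma_constant) {
    r <- y - mu_final$eta
    z <- eta_s + 0.5 * (r^2 * exp(-2 * eta_s) - 1)
    sig_final <- pwls_fit(sig_terms, z, 2 * weights,
                          lambdas = best$sig_fit$lambdas)
  }

  structure(list(
    family = "normal_locscale",
    mu = term_summary(mu_terms, mu_final),
    sigma = if (sigma_constant) list(constant = TRUE,
                                     log_sigma = best$eta_s[1]) else
      term_summary(sig_terms, sig_final),
    fitted_mu = mu_final$eta,
    fitted_log_sigma = if (sigma_constant) best$eta_s else sig_final$eta,
    converged = best$converged,
    algorithm = algorithm,
    n_iterations = total_iter,
    penalized_deviance = best$pdev,
    deviance_trace = best$pdev_trace,
    n = n, n_dropped_covariates = n_dropped,
    concurvity = concurvity_diag(mu_terms[[1]]$X, covariates),
    d_range = spec$range
  ), class = "locscale_fit")
}

term_summary <- function(terms, fit) {
  list(terms = lapply(terms, function(t)
         t[c("label", "spec", "Z", "cap")]),
       coefficients = fit$beta,
       lambdas = fit$lambdas,
       edf = fit$edf_term,
       Vb = fit$Vb,
       index = fit$index)
}

# Simultaneous (Cole-Green-type) fallback: joint penalized Newton step on
# (beta, gamma) using the observed information, including the mu/log-sigma
# cross block, with step-halving on the penalized deviance.
run_cg <- function(y, w, mu_terms, sig_terms, state, control) {
  Xm <- do.call(cbind, lapply(mu_terms, `[[`, "X"))
  Xs <- do.call(cbind, lapply(sig_terms, `[[`, "X"))
  beta <- state$mu_fit$beta
  gamma <- state$sig_fit$beta
  lam_m <- state$mu_fit$lambdas
  lam_s <- state$sig_fit$lambdas
  Pm <- block_penalty(mu_terms, lam_m)
  Ps <- block_penalty(sig_terms, lam_s)
  pdev_of <- function(beta, gamma) {
    normal_pdev(y, w, as.vector(Xm %*% beta), as.vector(Xs %*% gamma),
                as.numeric(crossprod(beta, Pm %*% beta)),
                as.numeric(crossprod(gamma, Ps %*% gamma)))
  }
  pdev <- pdev_of(beta, gamma)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(control$cg_iter)) {
    iters <- it
    eta_mu <- as.vector(Xm %*% beta)
    eta_s <- as.vector(Xs %*% gamma)
    r <- y - eta_mu
    e2 <- exp(-2 * eta_s)
    # score of -pdev/2 ... use gradient of pdev directly
    g_mu <- -2 * crossprod(Xm, w * r * e2) + 2 * Pm %*% beta
    g_s <- crossprod(Xs, w * (2 - 2 * r^2 * e2)) + 2 * Ps %*% gamma
    H_mm <- 2 * crossprod(Xm, (w * e2) * Xm) + 2 * Pm
    H_ss <- 4 * crossprod(Xs, (w * r^2 * e2) * Xs) + 2 * Ps
    H_ms <- 4 * crossprod(Xm, (w * r * e2) * Xs)
    H <- rbind(cbind(H_mm, H_ms), cbind(t(H_ms), H_ss))
    g <- c(as.vector(g_mu), as.vector(g_s))
    step_dir <- tryCatch(solve(H, g), error = function(e) {
      # observed information not PD: drop the cross block
      He <- rbind(cbind(H_mm, 0 * H_ms), cbind(0 * t(H_ms), H_ss))
      solve(He + 1e-8 * mean(diag(He)) * diag(nrow(He)), g)
    })
    step <- 1
    repeat {
      beta_t <- beta - step * step_dir[seq_along(beta)]
      gamma_t <- gamma - step * step_dir[-seq_along(beta)]
      pd <- pdev_of(beta_t, gamma_t)
      if (pd <= pdev + 1e-10 || step < 1e-6) break
      step <- step / 2
    }
    if (abs(pd - pdev) / (abs(pdev) + 0.1) < control$tol) {
      beta <- beta_t; gamma <- gamma_t; pdev <- pd
      converged <- TRUE
      break
    }
    if (pd > pdev) break  # no descent possible
    beta <- beta_t; gamma <- gamma_t; pdev <- pd
  }
  mu_fit <- state$mu_fit
  mu_fit$beta <- as.vector(beta)
  mu_fit$eta <- as.vector(Xm %*% beta)
  sig_fit <- state$sig_fit
  sig_fit$beta <- as.vector(gamma)
  sig_fit$eta <- as.vector(Xs %*% gamma)
  list(mu_fit = mu_fit, sig_fit = sig_fit, eta_mu = mu_fit$eta,
       eta_s = sig_fit$eta, pdev = pdev,
       pdev_trace = c(state$pdev_trace, pdev),
       converged = converged, iterations = iters)
}

#' Fit a penalized Bernoulli gradient model
#'
#' Penalized scoring (IRLS) fit of a smooth on the log-odds scale for a
#' binary outcome such as loneliness. The predicted variance is `p(1-p)` by
#' construction, so no separate SD smooth exists.
#'
#' @inheritParams fit_normal_locscale
#' @param y Binary 0/1 outcome.
#' @param lambda Optional fixed smoothing parameter (bypasses GCV).
#' @return Object of class `locscale_fit` with `family = "bernoulli"`.
#' @export
fit_bernoulli <- function(y, d, spec = spline_spec(), weights = NULL,
                          lambda = NULL, control = locscale_control()) {
  n <- length(y)
  stopifnot(length(d) == n, all(y %in% c(0, 1)))
  if (all(y == 0) || all(y == 1)) {
    stop("separation: response is all ", y[1], call. = FALSE)
  }
  if (is.null(weights)) weights <- rep.int(1, n)
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  terms <- list(smooth_term(d, spec, "urbanicity"))
  lam <- if (!is.null(lambda)) lambda else NA_real_
  p0 <- sum(weights * y) / sum(weights)
  eta <- rep(stats::qlogis(p0), n)
  fit <- NULL
  dev_old <- Inf
  converged <- FALSE
  trace <- numeric(0)
  for (it in 1:100) {
    p <- stats::plogis(eta)
    wi <- weights * p * (1 - p)
    z <- eta + (y - p) / pmax(p * (1 - p), 1e-10)
    frozen <- it > control$freeze_after
    fit <- pwls_fit(terms, z, wi,
                    lambdas = if (frozen) fit$lambdas else lam)
    eta <- pmin(pmax(fit$eta, -30), 30)
    p <- stats::plogis(eta)
    dev <- -2 * sum(weights * (y * log(pmax(p, 1e-12)) +
                               (1 - y) * log(pmax(1 - p, 1e-12)))) +
      fit$penalty_quadform
    if (frozen) trace <- c(trace, dev)
    if (frozen && abs(dev - dev_old) / (abs(dev_old) + 0.1) < control$tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  structure(list(
    family = "bernoulli",
    mu = term_summary(terms, fit),
    sigma = NULL,
    fitted_mu = stats::plogis(fit$eta),
    converged = converged,
    algorithm = "IRLS",
    n_iterations = it,
    penalized_deviance = dev,
    deviance_trace = trace,
    n = n, d_range = spec$range
  ), class = "locscale_fit")
}

#' @export
print.locscale_fit <- function(x, ...) {
  cat("Penalized location-scale gradient fit (", x$family, ")\n", sep = "")
  cat("  n =", x$n, " converged:", x$converged,
      " algorithm:", x$algorithm, "\n")
  cat("  mean smooth edf:", round(x$mu$edf, 3), "\n")
  if (!is.null(x$sigma) && is.null(x$sigma$constant)) {
    cat("  log-SD smooth edf:", round(x$sigma$edf, 3), "\n")
  }
  if (!is.null(x$concurvity)) {
    cat("  covariate concurvity with urbanicity (R^2):",
        paste(names(x$concurvity), round(x$concurvity, 3), collapse = ", "),
        "\n")
  }
  invisible(x)
}
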