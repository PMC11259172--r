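# Internal penalized weighted least-squares engine shared by the mean,
# log-SD and Bernoulli working-model updates. A model is a list of smooth
# terms; each term carries its own basis block, difference penalty, and
# smoothing parameter (selected by GCV, capped at the spec's max edf, or
# held fixed).

# One smooth term. `center = TRUE` applies the sum-to-zero reparameterization
# used for covariate smooths (the urbanicity smooth absorbs the intercept
# since B-spline rows sum to one).
smooth_term <- function(x, spec, label, center = FALSE) {
  B <- build_basis(x, spec)
  P <- penalty_matrix(ncol(B), spec$penalty_order)
  Z <- NULL
  if (center) {
    C <- matrix(colSums(B), ncol = 1L)
    Z <- qr.Q(qr(C), complete = TRUE)[, -1L, drop = FALSE]
    B <- B %*% Z
    P <- crossprod(Z, P %*% Z)
    P <- (P + t(P)) / 2
  }
  list(label = label, spec = spec, X = B, P = P, Z = Z,
       cap = spec$max_edf)
}

term_index <- function(terms) {
  p <- vapply(terms, function(t) ncol(t$X), integer(1))
  ends <- cumsum(p)
  starts <- ends - p + 1L
  Map(function(s, e) s:e, starts, ends)
}

block_penalty <- function(terms, lambdas) {
  p <- sum(vapply(terms, function(t) ncol(t$X), integer(1)))
  L <- matrix(0, p, p)
  idx <- term_index(terms)
  for (k in seq_along(terms)) {
    L[idx[[k]], idx[[k]]] <- lambdas[k] * terms[[k]]$P
  }
  L
}

# Penalized WLS fit of working response y with weights w on the terms.
# lambdas: numeric vector, NA entries selected by the smoothness criterion
# (then capped at the term's max edf). Returns coefficients, per-term edf,
# covariance (A + penalty)^{-1}, and the quadratic-form pieces needed
# upstream. criterion: "ubre" (default: Mallows-Cp with known unit
# dispersion, which is how every working model here is scaled), "gcv", or
# "bic". gcv_gamma inflates the edf cost (the device mgcv recommends
# against undersmoothing); 1.7 makes the smooths favour broad trends over
# small fluctuations, which is the analysis intent (cross-checked against
# simulation recovery, coverage and null-case behaviour).
pwls_fit <- function(terms, y, w, lambdas = NULL, criterion = "ubre",
                     gcv_gamma = 1.7) {
  X <- do.call(cbind, lapply(terms, `[[`, "X"))
  idx <- term_index(terms)
  A <- crossprod(X, X * w)
  b <- crossprod(X, y * w)
  sw <- sum(w)
  yWy <- sum(w * y^2)
  ridge <- 1e-8 * mean(diag(A)) * diag(ncol(A))

  solve_at <- function(lams) {
    M <- A + block_penalty(terms, lams) + ridge
    R <- tryCatch(chol(M), error = function(e) chol(M + 1e4 * ridge))
    Vb <- chol2inv(R)
    beta <- Vb %*% b
    Tm <- Vb %*% A
    edf_term <- vapply(idx, function(ii) sum(diag(Tm)[ii]), numeric(1))
    rss <- yWy - 2 * sum(beta * b) + sum(beta * (A %*% beta))
    rss <- max(rss, 1e-300)
    edf_tot <- min(sum(edf_term), sw - 1)
    crit <- switch(criterion,
      gcv = sw * rss / (sw - min(gcv_gamma * edf_tot, sw - 1))^2,
      ubre = rss + 2 * gcv_gamma * edf_tot,
      bic = sw * log(rss / sw) + log(sw) * edf_tot
    )
    list(beta = beta, Vb = Vb, edf_term = edf_term,
         edf_total = sum(edf_term), rss = rss, gcv = crit)
  }

  lam_ref <- vapply(seq_along(terms), function(k) {
    sum(diag(A[idx[[k]], idx[[k]], drop = FALSE])) /
      max(sum(diag(terms[[k]]$P)), 1e-300)
  }, numeric(1))

  if (is.null(lambdas)) lambdas <- rep(NA_real_, length(terms))
  sel <- is.na(lambdas)
  lambdas[sel] <- lam_ref[sel]  # starting value for sweeps

  if (any(sel)) {
    for (sweep in 1:2) {
      for (k in which(sel)) {
        grid <- lam_ref[k] * 10^seq(-7, 7, by = 0.5)
        gcvs <- vapply(grid, function(l) {
          lams <- lambdas; lams[k] <- l
          solve_at(lams)$gcv
        }, numeric(1))
        lambdas[k] <- grid[which.min(gcvs)]
      }
    }
    # enforce per-term edf caps by recalibrating lambda upward
    for (k in which(sel)) {
      cap <- terms[[k]]$cap
      if (is.finite(cap) && solve_at(lambdas)$edf_term[k] > cap + 0.005) {
        lo <- lambdas[k]
        hi <- lam_ref[k] * 1e12
        while (TRUE) {
          lams <- lambdas; lams[k] <- hi
          if (solve_at(lams)$edf_term[k] <= cap || hi > lam_ref[k] * 1e18) break
          hi <- hi * 100
        }
        for (i in 1:100) {
          mid <- sqrt(lo * hi)
          lams <- lambdas; lams[k] <- mid
          e <- solve_at(lams)$edf_term[k]
          if (abs(e - cap) < 0.005) break
          if (e > cap) lo <- mid else hi <- mid
        }
        lambdas[k] <- mid
      }
    }
  }

  fit <- solve_at(lambdas)
  pen <- block_penalty(terms, lambdas)
  list(beta = as.vector(fit$beta), lambdas = lambdas,
       edf_term = fit$edf_term, edf_total = fit$edf_total,
       Vb = fit$Vb, A = A, index = idx, X = X,
       eta = as.vector(X %*% fit$beta),
       penalty_quadform = as.numeric(crossprod(fit$beta, pen %*% fit$beta)),
       gcv = fit$gcv)
}

# Penalty quadratic form for an arbitrary coefficient vector under the
# lambdas of a previous pwls fit.
penalty_value <- function(terms, lambdas, beta) {
  as.numeric(crossprod(beta, block_penalty(terms, lambdas) %*% beta))
}
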