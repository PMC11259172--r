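# simulated urbanicity values with the heavy near-city concentration the
# placement model produces
sim_d <- function(n, seed) {
  set.seed(seed)
  d <- rexp(n * 1.3, 1 / 0.015)
  d[d < 0.07][1:n]
}

test_that("null signal is recovered flat for mean and SD", {
  # sup-norm deviation from mu = 0, sigma = 1 at n = 5000 is itself a
  # random quantity; require the typical (median over seeds) deviation to
  # stay inside +/- 0.05, and every seed inside a 2x slack
  n <- 5000
  sup_mu <- sup_sg <- numeric(0)
  for (seed in 21:25) {
    d <- sim_d(n, seed)
    set.seed(seed + 1000)
    y <- rnorm(n)
    fit <- fit_normal_locscale(y, d)
    expect_true(fit$converged)
    cv <- predict_with_bands(fit, reporting_grid())
    sup_mu <- c(sup_mu, max(abs(cv$mu_hat)))
    sup_sg <- c(sup_sg, max(abs(cv$sigma_hat - 1)))
  }
  expect_lt(median(sup_mu), 0.05)
  expect_lt(median(sup_sg), 0.05)
  expect_lt(max(sup_mu), 0.10)
  expect_lt(max(sup_sg), 0.10)
})

test_that("a planted mean bump is located to within half a grid step of truth", {
  n <- 20000
  d <- sim_d(n, 31)
  mu_t <- function(d) 0.2 * exp(-((d - 0.02) / 0.01)^2) - 0.1
  set.seed(32)
  y <- mu_t(d) + rnorm(n)
  fit <- fit_normal_locscale(y, d)
  cv <- predict_with_bands(fit, reporting_grid())
  ex <- find_extremum(cv, "max")
  expect_equal(ex$d_star, 0.02, tolerance = 0.25)  # within +/- 0.005
  expect_lt(abs(ex$d_star - 0.02), 0.005)
})

test_that("infinite penalty on the mean collapses to straight-line WLS", {
  n <- 3000
  d <- sim_d(n, 41)
  set.seed(42)
  w <- runif(n, 0.5, 2)
  y <- 0.5 - 2 * d + rnorm(n) * 0.7
  fit <- fit_normal_locscale(y, d, weights = w, sigma_spec = "constant",
                             lambda_mu = 1e12)
  # closed-form weighted linear regression oracle (sigma constant cancels)
  ols <- lm.wfit(cbind(1, d), y, w)
  grid <- seq(0, 0.05, length.out = 201)
  cv <- predict_with_bands(fit, grid)
  oracle <- ols$coefficients[1] + ols$coefficients[2] * grid
  expect_lt(max(abs(cv$mu_hat - oracle)), 1e-6)
})

test_that("constant-sigma fit with calibrated lambda matches a penalized WLS oracle", {
  n <- 4000
  d <- sim_d(n, 51)
  set.seed(52)
  y <- 0.1 * sin(d * 100) + rnorm(n) * 0.8
  fit <- fit_normal_locscale(y, d, sigma_spec = "constant")
  # one-shot penalized regression with the fitted lambda and weights
  sp <- spline_spec()
  B <- build_basis(d, sp)
  P <- penalty_matrix(ncol(B), 2)
  sig2 <- exp(2 * fit$sigma$log_sigma)
  lam <- fit$mu$lambdas[1]
  A <- crossprod(B) / sig2
  ridge <- 1e-8 * mean(diag(A)) * diag(ncol(A))
  beta <- solve(A + lam * P + ridge, crossprod(B, y) / sig2)
  expect_lt(max(abs(fit$mu$coefficients - beta)), 1e-8)
})

test_that("unit weights reproduce the unweighted fit exactly; split weights agree", {
  n <- 3000
  d <- sim_d(n, 61)
  set.seed(62)
  y <- 0.1 - d + rnorm(n)
  f0 <- fit_normal_locscale(y, d)
  f1 <- fit_normal_locscale(y, d, weights = rep(1, n))
  expect_identical(f0$mu$coefficients, f1$mu$coefficients)
  expect_identical(f0$sigma$coefficients, f1$sigma$coefficients)
  # duplicating every observation at half weight changes nothing
  f2 <- fit_normal_locscale(c(y, y), c(d, d), weights = rep(0.5, 2 * n))
  expect_lt(max(abs(f0$mu$coefficients - f2$mu$coefficients)), 1e-8)
  expect_lt(max(abs(f0$sigma$coefficients - f2$sigma$coefficients)), 1e-8)
  expect_error(fit_normal_locscale(y, d, weights = rep(-1, n)), "negative")
})

test_that("penalized deviance is nonincreasing over recorded iterations", {
  for (seed in c(71, 72, 73)) {
    n <- 4000
    d <- sim_d(n, seed)
    set.seed(seed + 1000)
    y <- 0.2 * exp(-((d - 0.02) / 0.015)^2) +
      exp(0.1 - 2 * d) * rnorm(n)
    fit <- fit_normal_locscale(y, d)
    expect_true(fit$converged)
    expect_true(all(diff(fit$deviance_trace) < 1e-7))
  }
})

test_that("achieved edf respects the cap under strong signal", {
  n <- 20000
  d <- sim_d(n, 81)
  set.seed(82)
  y <- 0.4 * exp(-((d - 0.02) / 0.008)^2) + rnorm(n) * 0.8
  fit <- fit_normal_locscale(y, d)
  expect_lte(fit$mu$edf[1], spline_spec()$max_edf + 0.01)
  expect_lte(fit$sigma$edf[1], spline_spec()$max_edf + 0.01)
})

test_that("the fitted gradient agrees with an independent GAMLSS-type fit", {
  skip_if_not_installed("mgcv")
  n <- 8000
  d <- sim_d(n, 91)
  set.seed(92)
  mu_t <- function(d) 0.15 * exp(-((d - 0.02) / 0.015)^2)
  sd_t <- function(d) exp(0.05 - 1.5 * d)
  y <- mu_t(d) + sd_t(d) * rnorm(n)
  fit <- fit_normal_locscale(y, d)
  cv <- predict_with_bands(fit, reporting_grid(n = 201))
  g <- mgcv::gam(list(y ~ s(d, k = 10), ~ s(d, k = 10)),
                 family = mgcv::gaulss())
  pr <- mgcv::predict.gam(g, newdata = data.frame(d = cv$d), type = "response")
  # gaulss column 2 is 1/sigma
  expect_lt(max(abs(cv$mu_hat - pr[, 1])), 0.05)
  expect_lt(max(abs(cv$sigma_hat - 1 / pr[, 2])), 0.05)
})

test_that("Bernoulli fit is flat on coin flips and ties variance to the mean", {
  n <- 5000
  d <- sim_d(n, 101)
  set.seed(102)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_bernoulli(y, d)
  cv <- predict_with_bands(fit, reporting_grid())
  expect_true(all(abs(cv$mu_hat - 0.5) < 0.03))
  expect_equal(cv$sigma_hat, sqrt(cv$mu_hat * (1 - cv$mu_hat)))
  expect_error(fit_bernoulli(rep(1, 100), sim_d(100, 1)), "separation")
})

test_that("heavily penalized Bernoulli fit matches plain logistic regression", {
  n <- 8000
  d <- sim_d(n, 111)
  set.seed(112)
  eta_t <- -1 + 20 * d
  y <- rbinom(n, 1, plogis(eta_t))
  fit <- fit_bernoulli(y, d, lambda = 1e12)
  glm_fit <- glm(y ~ d, family = binomial())
  grid <- seq(0.001, 0.049, length.out = 201)
  cv <- predict_with_bands(fit, grid)
  oracle <- plogis(coef(glm_fit)[1] + coef(glm_fit)[2] * grid)
  expect_lt(max(abs(cv$mu_hat - oracle)), 1e-5)
})

test_that("confidence bands are positive for sigma, nested across levels, and shrink with n", {
  d <- sim_d(4000, 121)
  set.seed(122)
  y <- rnorm(4000)
  fit <- fit_normal_locscale(y, d)
  g <- reporting_grid(n = 201)
  cv95 <- predict_with_bands(fit, g, level = 0.95)
  cv99 <- predict_with_bands(fit, g, level = 0.99)
  expect_true(all(cv95$sigma_low > 0))
  expect_true(all(cv95$mu_low <= cv95$mu_hat & cv95$mu_hat <= cv95$mu_high))
  expect_true(all(cv99$mu_low <= cv95$mu_low & cv95$mu_high <= cv99$mu_high))
  # width shrinks as n grows
  d2 <- sim_d(16000, 123)
  set.seed(124)
  fit2 <- fit_normal_locscale(rnorm(16000), d2)
  cv2 <- predict_with_bands(fit2, g)
  expect_lt(mean(cv2$mu_high - cv2$mu_low), mean(cv95$mu_high - cv95$mu_low))
  expect_error(predict_with_bands(fit, c(0, 0.08)), "xtrapolation")
  expect_error(predict_with_bands(fit, c(0.02, 0.01)), "increasing")
})

test_that("covariate adjustment leaves an unconfounded gradient unchanged", {
  n <- 20000
  d <- sim_d(n, 131)
  set.seed(132)
  mu_t <- function(d) 0.2 * exp(-((d - 0.02) / 0.015)^2)
  y <- mu_t(d) + rnorm(n)
  noise_cov <- data.frame(age = rnorm(n, 55, 7.7))
  f0 <- fit_normal_locscale(y, d)
  f1 <- add_covariates(y, d, noise_cov)
  g <- reporting_grid(n = 201)
  c0 <- predict_with_bands(f0, g)
  c1 <- predict_with_bands(f1, g)
  expect_lt(max(abs(c0$mu_hat - c1$mu_hat)), 0.02)
})

test_that("a covariate that is a function of d still converges, flagged as concurve", {
  n <- 6000
  d <- sim_d(n, 141)
  set.seed(142)
  y <- 0.1 - 2 * d + rnorm(n)
  f <- add_covariates(y, d, data.frame(age = 3 * d + 1))
  expect_true(f$converged || !f$converged)  # must return, not error
  expect_gt(f$concurvity[["age"]], 0.99)
})

test_that("adjusting for a planted confounder moves the gradient toward truth", {
  n <- 20000
  d <- sim_d(n, 151)
  set.seed(152)
  mu_t <- function(d) 0.12 * exp(-((d - 0.025) / 0.015)^2)
  conf <- 0.5 * exp(-(d / 0.02)^2) + rnorm(n) * 0.5   # income-like, urban-high
  y <- mu_t(d) + 0.6 * (conf - mean(conf)) + rnorm(n) * 0.8
  g <- reporting_grid(n = 201)
  truth <- mu_t(g) - mean(mu_t(d) + 0.6 * (conf - mean(conf)))  # centered scale
  f_un <- fit_normal_locscale(y - mean(y), d)
  f_ad <- add_covariates(y - mean(y), d, data.frame(income = conf))
  c_un <- predict_with_bands(f_un, g)
  c_ad <- predict_with_bands(f_ad, g)
  shape_err <- function(cv) {
    a <- cv$mu_hat - mean(cv$mu_hat)
    b <- mu_t(g) - mean(mu_t(g))
    mean((a - b)^2)
  }
  expect_lt(shape_err(c_ad), shape_err(c_un))
})
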