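fake_curve <- function(d, mu, sigma = rep(1, length(d))) {
  structure(data.frame(d = d, mu_hat = mu, mu_low = mu - 0.1,
                       mu_high = mu + 0.1, sigma_hat = sigma,
                       sigma_low = sigma * 0.9, sigma_high = sigma * 1.1),
            class = c("gradient_curve", "data.frame"),
            family = "normal_locscale")
}

test_that("the method of differences finds interior extrema and rejects boundaries", {
  d <- seq(0, 0.05, length.out = 501)
  cv <- fake_curve(d, -(d - 0.02)^2)
  ex <- find_extremum(cv, "max")
  expect_equal(ex$kind, "maximum")
  expect_equal(ex$d_star, d[which.min(abs(d - 0.02))])

  # monotone curve: none
  ex2 <- find_extremum(fake_curve(d, 3 * d), "max")
  expect_equal(ex2$kind, "none")
  expect_true(is.na(ex2$d_star))
  # boundary extremum in the requested sense: none
  ex3 <- find_extremum(fake_curve(d, -3 * d), "max")
  expect_equal(ex3$kind, "none")

  # min sense on a V-shaped SD curve
  exm <- find_extremum(fake_curve(d, 0 * d, sigma = 1 + (d - 0.03)^2), "min",
                       value_col = "sigma_hat")
  expect_equal(exm$d_star, d[which.min(abs(d - 0.03))])

  expect_error(find_extremum(fake_curve(d[1:100], d[1:100]), "max"),
               "coarse")
})

test_that("interior optima agree with the grid argmax oracle on random smooth curves", {
  d <- seq(0, 0.05, length.out = 501)
  set.seed(17)
  for (i in 1:30) {
    coefs <- rnorm(4, sd = c(1, 30, 600, 8000))
    v <- coefs[1] + coefs[2] * d + coefs[3] * d^2 + coefs[4] * d^3
    ex <- find_extremum(fake_curve(d, v), "max")
    am <- which.max(v)
    if (am > 1 && am < length(d)) {
      expect_equal(ex$d_star, d[am])
    } else {
      expect_equal(ex$kind, "none")
    }
  }
  # random monotone curves always give none
  for (i in 1:20) {
    v <- cumsum(abs(rnorm(501))) * sample(c(-1, 1), 1)
    expect_equal(find_extremum(fake_curve(d, v), "max")$kind, "none")
  }
})

test_that("effect sizes read differences in z between center and optimum", {
  d <- seq(0, 0.05, length.out = 501)
  expect_equal(effect_size(fake_curve(d, rep(0.3, 501)), NA), 0)
  v <- -0.10 + 0.15 * exp(-((d - 0.02) / 0.01)^2)
  cv <- fake_curve(d, v)
  ex <- find_extremum(cv, "max")
  # hand computation: v(0) = -0.10 + 0.15*exp(-4), peak value 0.05
  expect_equal(effect_size(cv, ex$d_star), 0.15 - 0.15 * exp(-4),
               tolerance = 1e-3)
  # hand arithmetic: z(0) = -0.10, z(d_star) = 0.05
  v2 <- rep(-0.10, 501); v2[200] <- 0.05
  expect_equal(effect_size(fake_curve(d, v2), d[200]), 0.15)
  # no interior optimum: min-to-max swing
  expect_equal(effect_size(fake_curve(d, 2 * d), NA), 0.1)
})

test_that("km conversion reproduces the published table arithmetic", {
  expect_equal(to_km(0.025, 8800000), 74)
  expect_equal(to_km(0.025, 230000), 12)
  expect_equal(to_km(0, 5e6), 0)
  # linear in d_star, monotone in population
  expect_equal(to_km(0.05, 640000, digits = NA), 2 * to_km(0.025, 640000, digits = NA))
  expect_lt(to_km(0.02, 1e5), to_km(0.02, 1e6))
})

test_that("the peaks table maps curve kinds, senses and km columns correctly", {
  d <- seq(0, 0.05, length.out = 501)
  mu <- 0.1 * exp(-((d - 0.02) / 0.01)^2)
  sg <- 1.05 - 0.08 * exp(-((d - 0.03) / 0.012)^2)
  curves <- list(meaningful_life = fake_curve(d, mu, sg))
  pk <- peaks_table(curves)
  expect_equal(nrow(pk), 2L)
  mean_row <- pk[pk$curve_kind == "mean", ]
  sd_row <- pk[pk$curve_kind == "sd", ]
  expect_equal(mean_row$d_star, 0.02, tolerance = 1e-6)
  expect_equal(sd_row$d_star, 0.03, tolerance = 1e-6)
  expect_equal(mean_row$km_London, to_km(0.02, 8800000))
  expect_equal(mean_row$km_Reading, to_km(0.02, 230000))

  # loneliness: lower is healthy, so the mean optimum is the minimum,
  # and no SD row is produced for the Bernoulli family
  p <- 0.25 - 0.05 * exp(-((d - 0.024) / 0.012)^2)
  lon <- structure(data.frame(d = d, mu_hat = p, mu_low = p, mu_high = p,
                              sigma_hat = sqrt(p * (1 - p)),
                              sigma_low = sqrt(p * (1 - p)),
                              sigma_high = sqrt(p * (1 - p))),
                   class = c("gradient_curve", "data.frame"),
                   family = "bernoulli", p_marginal = 0.23)
  pk2 <- peaks_table(list(loneliness = lon))
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$extremum_kind, "minimum")
  expect_equal(pk2$d_star, 0.024, tolerance = 1e-6)
  # probability difference expressed in SD units of the binary item:
  # p(0) = 0.25 - 0.05*exp(-4), so the drop to the optimum is
  # 0.05*(1 - exp(-4))
  expect_equal(pk2$effect_size,
               0.05 * (1 - exp(-4)) / sqrt(0.23 * 0.77), tolerance = 1e-6)
})
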