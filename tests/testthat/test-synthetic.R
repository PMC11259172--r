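test_that("generation is deterministic given the seed and leaves the RNG alone", {
  c1 <- generate_cohort(synthetic_config(seed = 5, n_participants = 2000))
  set.seed(999)
  before <- .Random.seed
  c2 <- generate_cohort(synthetic_config(seed = 5, n_participants = 2000))
  expect_identical(.Random.seed, before)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$districts, c2$districts)
  expect_identical(c1$latent, c2$latent)

  c3 <- generate_cohort(synthetic_config(seed = 6, n_participants = 2000))
  expect_false(identical(c1$participants, c3$participants))
})

test_that("cohort demographics match the study population moments", {
  coh <- generate_cohort(synthetic_config(seed = 7, n_participants = 20000))
  p <- coh$participants
  expect_equal(mean(p$age), 55, tolerance = 0.2 / 55)
  expect_lt(abs(sd(p$age) - 7.7), 0.2)
  expect_lt(abs(mean(p$sex == "female") - 0.57), 0.01)
})

test_that("discretization conserves counts and respects answer structures", {
  coh <- generate_cohort(synthetic_config(seed = 8, n_participants = 10000))
  p <- coh$participants
  codes <- special_codes()
  for (it in item_specs()$item) {
    v <- p[[it]]
    expect_equal(length(v), 10000)
    valid <- switch(item_specs()$response_type[item_specs()$item == it],
                    likert6 = 1:6, income_bands = 1:5, binary = 0:1)
    special <- unlist(codes)
    expect_true(all(v %in% c(valid, special)))
    # category counts plus special codes account for every participant
    expect_equal(sum(table(v)), 10000L)
  }
  # planted special codes land only where the survey design has them
  expect_false(any(p$happiness == codes$dontknow))
  expect_true(any(p$meaningful_life == codes$dontknow))
  expect_true(any(p$job_satisfaction == codes$jobless))
  expect_false(any(p$income == codes$jobless))
  # satisfaction histograms are left-skewed (most responses in the top half)
  tab <- table(factor(p$happiness[p$happiness %in% 1:6], levels = 1:6))
  expect_gt(sum(tab[4:6]), sum(tab[1:3]))
})

test_that("binned latent SD tracks the planted sigma curve", {
  coh <- generate_cohort(synthetic_config(seed = 9, n_participants = 20000))
  d <- coh$assignments$d
  lat <- coh$latent$income
  bins <- cut(d, c(0, 0.01, 0.02, 0.03, 0.04, 0.05))
  emp_sd <- tapply(lat, bins, sd)
  mids <- c(0.005, 0.015, 0.025, 0.035, 0.045)
  truth_sd <- truth_curve(coh$truth, "income", "sigma", mids)
  ns <- tapply(lat, bins, length)
  # within ~4 standard errors of a sample SD
  tol <- 4 * truth_sd / sqrt(2 * (ns - 1))
  expect_true(all(abs(emp_sd - truth_sd) < tol))
})

test_that("placement concentrates participants near cities on the adjusted scale", {
  coh <- generate_cohort(synthetic_config(seed = 10, n_participants = 10000))
  d <- coh$assignments$d
  # near-city fraction is 80%; their d is exponential with mean 0.012
  expect_gt(mean(d < 0.05), 0.75)
  expect_lt(median(d[d < 0.07]), 0.02)
  expect_true(all(coh$assignments$nearest_city %in% coh$gazetteer$name))
})

test_that("the planted confounder raises urban incomes and is absent at strength 0", {
  cfg0 <- synthetic_config(seed = 12, n_participants = 20000)
  cfg1 <- plant_confounder(cfg0, 0.6)
  c0 <- generate_cohort(cfg0)
  c1 <- generate_cohort(plant_confounder(cfg0, 0))
  expect_identical(c0$participants, c1$participants)

  cc <- generate_cohort(cfg1)
  d <- cc$assignments$d
  inc <- cc$latent$income
  expect_gt(mean(inc[d < 0.005]), mean(inc[d > 0.03]))
  # financial satisfaction inherits the income signal
  fin_conf <- cc$latent$financial_satisfaction
  fin_base <- c0$latent$financial_satisfaction
  expect_gt(cor(fin_conf, cc$latent$income), cor(fin_base, c0$latent$income))
  expect_error(plant_confounder(cfg0, NaN), "finite")
})

test_that("cohort files round-trip through CSV", {
  coh <- generate_cohort(synthetic_config(seed = 13, n_participants = 500))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  gaz <- read.csv(file.path(dir, "gazetteer.csv"))
  expect_equal(gaz$population, coh$gazetteer$population)
  back <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back), 500)
  expect_equal(back$happiness, coh$participants$happiness)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$meaningful_life$mu$amplitude, 0.2)
})
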