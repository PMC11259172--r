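test_that("nearest-city assignment matches the exhaustive oracle", {
  for (seed in 1:3) {
    gaz <- random_gazetteer(30, seed)
    pp <- random_participants(100, seed + 100)
    got <- assign_nearest(pp, gaz)
    oracle <- brute_assign(pp, gaz)
    expect_identical(got$nearest_city, gaz$name[oracle[, "city"]])
    expect_equal(got$d, unname(oracle[, "d"]))
    expect_equal(got$raw_km, unname(oracle[, "raw"]))
  }
})

test_that("assignment happens on the adjusted scale (Reading beats London)", {
  gaz <- gazetteer(data.frame(
    name = c("London", "Reading"),
    easting = c(55000, 0), northing = c(0, 0),
    population = c(8.8e6, 230000)), coords = "planar")
  # participant at Reading's center, 55 km from London
  p <- data.frame(participant_id = "p1", easting = 0, northing = 0)
  a <- assign_nearest(p, gaz)
  expect_identical(a$nearest_city, "Reading")
  expect_equal(a$d, 0)
  # yet London's adjusted distance would only have been ~0.0185
  expect_equal(55 / sqrt(8.8e6), 0.0185, tolerance = 1e-2)
})

test_that("population rescaling by k^2 scales d by 1/k, assignments fixed", {
  gaz <- random_gazetteer(12, 5)
  pp <- random_participants(60, 6)
  a1 <- assign_nearest(pp, gaz)
  gaz2 <- gaz
  gaz2$population <- gaz$population * 9
  a2 <- assign_nearest(pp, gaz2)
  expect_identical(a1$nearest_city, a2$nearest_city)
  expect_equal(a2$d, a1$d / 3)
})

test_that("gazetteer filtering is inclusive, order-preserving and monotone", {
  gaz <- gazetteer(data.frame(
    name = c("Reading", "town"), easting = c(0, 1000), northing = c(0, 0),
    population = c(230000, 120000)), coords = "planar")
  expect_identical(filter_gazetteer(gaz, 200000)$name, "Reading")
  gaz2 <- gazetteer(data.frame(
    name = c("a", "b"), easting = c(0, 1), northing = c(0, 1),
    population = c(50000, 90000)), coords = "planar")
  expect_identical(filter_gazetteer(gaz2, 50000)$name, gaz2$name)
  expect_error(filter_gazetteer(gaz, 1e9), "cannot proceed")

  # raising the threshold never adds a city, and never decreases any d
  gaz <- random_gazetteer(20, 9)
  pp <- random_participants(40, 10)
  prev <- gaz
  d_prev <- assign_nearest(pp, prev)$d
  for (thr in c(2e5, 5e5, 1e6, 2e6)) {
    cur <- filter_gazetteer(gaz, thr)
    expect_true(all(cur$name %in% prev$name))
    d_cur <- assign_nearest(pp, cur)$d
    expect_true(all(d_cur >= d_prev - 1e-12))
    prev <- cur
    d_prev <- d_cur
  }
})

test_that("assignment works with geographic coordinates too", {
  gaz <- gazetteer(data.frame(
    name = c("big", "small"), lon = c(0, 1), lat = c(51, 51),
    population = c(1e6, 1e5)), coords = "lonlat")
  p <- data.frame(participant_id = "x", lon = 0.99, lat = 51.01)
  a <- assign_nearest(p, gaz)
  expect_identical(a$nearest_city, "small")
  expect_gt(a$raw_km, 0)
  expect_error(assign_nearest(p, gaz[0, ]), "empty")
})

test_that("log-density scoring flags outliers and missing districts", {
  dist_tab <- data.frame(district_id = sprintf("D%03d", 1:1000),
                         density_per_km2 = exp(seq(log(0.5), log(8000),
                                                   length.out = 1000)))
  pp <- data.frame(participant_id = sprintf("p%04d", 1:1001),
                   district_id = c(sprintf("D%03d", 1:1000), "NOPE"))
  ds <- log_density(pp, dist_tab, outlier_quantile = 0.001)
  expect_equal(ds$log_density[1], log(0.5))
  counts <- attr(ds, "counts")
  expect_equal(unname(counts["missing_district"]), 1L)
  # sort-based oracle for the excluded count
  ld <- log(dist_tab$density_per_km2)
  cut <- quantile(ld, 0.001, names = FALSE)
  expect_equal(unname(counts["excluded_outlier"]), sum(ld < cut))
  expect_true(all(is.finite(ds$log_density[ds$status == "included"])))
  # log(1) = 0 and log(e^2) = 2
  t2 <- data.frame(district_id = c("a", "b"),
                   density_per_km2 = c(1, exp(2)))
  p2 <- data.frame(participant_id = c("1", "2"),
                   district_id = c("a", "b"))
  expect_equal(log_density(p2, t2, 0)$log_density, c(0, 2))
})
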