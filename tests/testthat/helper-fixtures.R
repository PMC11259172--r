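# shared fixtures and independent oracles

# spherical law of cosines, an independent great-circle formula
slc_km <- function(p, q, radius_km = 6371.0088) {
  to_rad <- pi / 180
  lat1 <- p[2] * to_rad; lat2 <- q[2] * to_rad
  dlon <- (q[1] - p[1]) * to_rad
  c_ang <- sin(lat1) * sin(lat2) + cos(lat1) * cos(lat2) * cos(dlon)
  radius_km * acos(pmin(pmax(c_ang, -1), 1))
}

# brute-force nearest-city assignment over all (participant, city) pairs
brute_assign <- function(participants, cities, normalization = "sqrt_population") {
  div <- if (normalization == "sqrt_population") sqrt(cities$population) else
    sqrt(cities$area_km2 / pi)
  t(sapply(seq_len(nrow(participants)), function(i) {
    raw <- sqrt((participants$easting[i] - cities$easting)^2 +
                (participants$northing[i] - cities$northing)^2) / 1000
    adj <- raw / div
    # lexicographic tie-break on name
    best <- order(adj, cities$name)[1]
    c(city = best, raw = raw[best], d = adj[best])
  }))
}

random_gazetteer <- function(n, seed) {
  set.seed(seed)
  gazetteer(data.frame(
    name = sprintf("city%02d", sample(n)),
    easting = runif(n, 0, 8e5),
    northing = runif(n, 0, 8e5),
    population = round(runif(n, 5e4, 5e6)),
    area_km2 = round(runif(n, 5e4, 5e6)) / 4000,
    stringsAsFactors = FALSE
  ), coords = "planar")
}

random_participants <- function(n, seed) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    easting = runif(n, 0, 8e5),
    northing = runif(n, 0, 8e5),
    stringsAsFactors = FALSE
  )
}

# a small, quick synthetic cohort for pipeline-shape tests
small_cohort <- function(seed = 11, n = 4000) {
  generate_cohort(synthetic_config(seed = seed, n_participants = n))
}
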