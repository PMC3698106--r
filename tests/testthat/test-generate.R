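test_that("zip generation is seeded, positive and rescaled to the target", {
  cfg <- generator_config(n_zips = 50, n_sites = 10,
                          n_sites_from_population_centers = 4,
                          population_total = 1e6, seed = 11)
  z1 <- generate_zips(cfg)
  z2 <- generate_zips(cfg)
  expect_identical(z1, z2)
  expect_equal(nrow(z1), 50)
  expect_true(all(z1$population > 0))
  expect_equal(sum(z1$population), 1e6)
  expect_true(all(z1$x_km >= 0 & z1$x_km <= cfg$region_extent_km))
})

test_that("candidate selection solves the 1-median on small inputs", {
  # 3 collinear zips, equal weight: middle zip wins
  zips <- data.frame(id = c("Z1", "Z2", "Z3"), x_km = c(0, 10, 20), y_km = 0,
                     population = c(1, 1, 1))
  cfg <- generator_config(n_zips = 3, n_sites = 1,
                          n_sites_from_population_centers = 0,
                          coverage_time_min = 1e6, seed = 1)
  s <- select_candidate_sites(zips, cfg)
  expect_equal(s$x_km, 10)

  # matches exhaustive 1-median on a seeded 12-zip cloud
  cfg12 <- generator_config(n_zips = 12, n_sites = 1,
                            n_sites_from_population_centers = 0,
                            coverage_time_min = 1e6, seed = 5)
  z <- generate_zips(cfg12)
  s1 <- select_candidate_sites(z, cfg12)
  costs <- vapply(seq_len(12), function(i)
    sum(z$population * sqrt((z$x_km - z$x_km[i])^2 + (z$y_km - z$y_km[i])^2)),
    numeric(1))
  expect_equal(s1$x_km, z$x_km[which.min(costs)])
  expect_equal(s1$y_km, z$y_km[which.min(costs)])
})

test_that("site saturation and coverage guarantees hold", {
  cfg <- generator_config(n_zips = 8, n_sites = 8,
                          n_sites_from_population_centers = 0,
                          coverage_time_min = 1e6, seed = 3)
  z <- generate_zips(cfg)
  s <- select_candidate_sites(z, cfg)
  expect_equal(nrow(s), 8)  # one site per zip, weighted travel 0
  expect_equal(sort(s$x_km), sort(z$x_km))

  cfg2 <- generator_config(n_zips = 60, n_sites = 8,
                           n_sites_from_population_centers = 3, seed = 9)
  z2 <- generate_zips(cfg2)
  s2 <- select_candidate_sites(z2, cfg2)
  radius <- (cfg2$coverage_time_min - cfg2$coverage_slack_min) / 60 *
    cfg2$speed_kmh / cfg2$road_factor
  dmin <- apply(sqrt(outer(z2$x_km, s2$x_km, "-")^2 +
                     outer(z2$y_km, s2$y_km, "-")^2), 1, min)
  expect_true(all(dmin <= radius + 1e-9))
})

test_that("drive times follow distance, detour factor and speed", {
  zips <- data.frame(id = "Z1", x_km = 0, y_km = 0, population = 1)
  sites <- data.frame(id = c("S1", "S2"), x_km = c(60, 0), y_km = 0)
  cfg <- generator_config(n_zips = 2, n_sites = 2,
                          n_sites_from_population_centers = 0,
                          road_factor = 1, speed_kmh = 60,
                          travel_noise_sd_min = 0, seed = 1)
  tt <- build_travel_matrix(zips, sites, cfg)
  expect_equal(tt[1, 1], 60)   # 60 km at 60 km/h
  expect_equal(tt[1, 2], 0)    # co-located pair stays at zero
  cfg$travel_noise_sd_min <- 2
  tt2 <- build_travel_matrix(zips, sites, cfg)
  expect_true(all(is.finite(tt2)) && all(tt2 >= 0))
  expect_equal(tt2[1, 2], 0)   # exact zero preserved under noise
})

test_that("demand spreading is proportional and conserves admissions exactly", {
  groups <- data.frame(id = 1L, n_patients = 100L)
  zips <- data.frame(id = c("Z1", "Z2"), population = c(75, 25))
  d <- spread_demand(groups, zips)
  expect_equal(as.vector(d), c(75, 25))

  one <- spread_demand(groups, data.frame(id = "Z1", population = 10))
  expect_equal(as.vector(one), 100)

  g30 <- load_diagnosis_groups()
  z <- generate_zips(generator_config(n_zips = 97, n_sites = 10,
                                      n_sites_from_population_centers = 5,
                                      seed = 2))
  dm <- spread_demand(g30, z)
  expect_identical(unname(colSums(dm)), as.numeric(g30$n_patients))
  expect_true(all(dm >= 0))
})

test_that("resource usage respects care-class rules and the seed", {
  g <- load_diagnosis_groups()
  u1 <- generate_usage(g, seed = 4)
  u2 <- generate_usage(g, seed = 4)
  expect_identical(u1, u2)
  expect_true(all(u1 >= 0))
  chronic <- g$care_class == "chronic"
  expect_true(all(u1[chronic, "OR"] == 0))
  expect_true(all(u1[chronic, "ICU"] == 0))
  expect_true(all(u1[!chronic, "OR"] > 0))
})

test_that("generated instances satisfy all instance invariants", {
  cfg <- generator_config(n_zips = 40, n_sites = 8,
                          n_sites_from_population_centers = 4, seed = 21)
  inst <- generate_instance(cfg)
  expect_s3_class(inst, "hosp_instance")
  expect_silent(validate_instance(inst))
  expect_equal(nrow(inst$groups), 30)
  expect_equal(dim(inst$travel), c(40, 8))
})
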