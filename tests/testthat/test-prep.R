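test_that("cleaning deduplicates and enforces the at-sea / in-bounds rules", {
  g <- tiny_grid()
  land <- which(g$land_mask, arr.ind = TRUE)[1, ]
  sea <- which(arcbiodiv:::ocean_mask(g), arr.ind = TRUE)
  sea <- sea[nrow(sea), ]   # a guaranteed ocean cell
  sea_lon <- g$lon_centers[sea[2]] + 0.3
  sea_lat <- g$lat_centers[sea[1]] + 0.2
  raw <- data.frame(
    species_id = "s1", guild = "meso",
    longitude = c(sea_lon, sea_lon, g$lon_centers[land[2]], 0.5, 100),
    latitude = c(sea_lat, sea_lat, g$lat_centers[land[1]], 49, 55),
    year = 2000L, source = "x")
  out <- clean_occurrences(raw, g)
  expect_equal(nrow(out), 1)           # dup removed, land/out-of-bounds dropped
  expect_equal(out$longitude, sea_lon)
  lg <- attr(out, "log")
  expect_equal(unname(lg["duplicates"]), 1)
  expect_equal(nrow(clean_occurrences(raw[0, ], g)), 0)
})

test_that("thinning enforces the minimum-distance contract on derived cases", {
  # 0.4 degrees latitude apart: haversine about 44.5 km < 100 -> one survives
  two_close <- data.frame(species_id = "s", year = 2000L,
                          longitude = c(0, 0), latitude = c(55, 55.4))
  expect_equal(haversine_km(0, 55, 0, 55.4), 44.5, tolerance = 0.01)
  expect_equal(nrow(thin_occurrences(two_close, 100, seed = 1)), 1)
  # 2 degrees apart: about 222.4 km -> both survive
  two_far <- data.frame(species_id = "s", year = 2000L,
                        longitude = c(0, 0), latitude = c(55, 57))
  expect_equal(nrow(thin_occurrences(two_far, 100, seed = 1)), 2)
  # single point survives
  expect_equal(nrow(thin_occurrences(two_far[1, ], 100, seed = 1)), 1)
  expect_error(thin_occurrences(two_far, -1), "positive")
})

test_that("thinning yields no close pairs and is idempotent", {
  set.seed(21)
  occ <- data.frame(species_id = "s", year = 2000L,
                    longitude = runif(120, -10, 10),
                    latitude = runif(120, 52, 60))
  th <- thin_occurrences(occ, 100, n_reps = 5, seed = 2)
  d <- arcbiodiv:::cross_dist_km(th$longitude, th$latitude,
                                 th$longitude, th$latitude)
  diag(d) <- Inf
  expect_gte(min(d), 100)
  again <- thin_occurrences(th, 100, n_reps = 5, seed = 99)
  expect_equal(nrow(again), nrow(th))
  expect_identical(thin_occurrences(occ, 100, n_reps = 5, seed = 2), th)
})

test_that("environmental profiles are per-variable presence ranges", {
  pres <- data.frame(SSST = c(2, 5, 8), SSIC = c(10, 40, 20))
  prof <- build_env_profile(pres, c("SSST", "SSIC"))
  expect_equal(prof$SSST, c(2, 8))
  expect_equal(prof$SSIC, c(10, 40))
  one <- build_env_profile(pres[2, ], "SSST")
  expect_equal(one$SSST, c(5, 5))
  expect_error(build_env_profile(pres[0, ], "SSST"), "zero presences")
})

test_that("pseudo-absences respect buffer, profile rule and pool limits", {
  env <- tiny_env()
  g <- env$grid
  pres <- data.frame(species_id = "s", year = 2000L,
                     longitude = c(0, 5), latitude = c(55, 57))
  pa <- sample_pseudoabsences(g, env, pres, 2000, n_target = 50,
                              buffer_km = 100, mode = "random",
                              variables = c("SSST", "SSIC"), seed = 1)
  d <- arcbiodiv:::cross_dist_km(pa$longitude, pa$latitude,
                                 pres$longitude, pres$latitude)
  expect_gt(min(d), 100)
  expect_equal(nrow(pa), 50)
  expect_true(all(pa$label == "pseudo_absence"))
  # profiled mode: every draw outside the occupied range on >= 1 variable
  prof <- list(SSST = c(-100, 100), SSIC = c(0, 14.9))  # SSST never excludes
  pp <- sample_pseudoabsences(g, env, pres, 2000, n_target = 30,
                              buffer_km = 100, mode = "profiled",
                              profile = prof, variables = c("SSST", "SSIC"),
                              seed = 2)
  expect_true(all(pp$SSIC > 14.9))
  # pool-limited draw warns and returns the pool
  expect_warning(
    big <- sample_pseudoabsences(g, env, pres, 2000, n_target = 1e5,
                                 buffer_km = 100, mode = "random",
                                 variables = "SSST", seed = 3),
    "smaller than n_target")
  expect_lt(nrow(big), 1e5)
  # empty pool errors
  expect_error(
    sample_pseudoabsences(g, env, pres, 2000, n_target = 10,
                          buffer_km = 100, mode = "profiled",
                          profile = list(SSST = c(-1e6, 1e6),
                                         SSIC = c(-1e6, 1e6)),
                          variables = "SSST", seed = 4),
    "no eligible cells")
  # determinism and shared eligibility support across seeds
  a <- sample_pseudoabsences(g, env, pres, 2000, 40, mode = "random",
                             variables = "SSST", seed = 5)
  b <- sample_pseudoabsences(g, env, pres, 2000, 40, mode = "random",
                             variables = "SSST", seed = 5)
  expect_identical(a, b)
  c2 <- sample_pseudoabsences(g, env, pres, 2000, 40, mode = "random",
                              variables = "SSST", seed = 6)
  dmin <- arcbiodiv:::cross_dist_km(c2$longitude, c2$latitude,
                                    pres$longitude, pres$latitude)
  expect_gt(min(dmin), 100)
  expect_error(sample_pseudoabsences(g, env, pres, 2000, 10,
                                     mode = "profiled", variables = "SSST"),
               "requires a profile")
})

test_that("training sets combine labels with complete covariates", {
  env <- tiny_env()
  pres <- data.frame(species_id = "s", year = 2000L,
                     longitude = c(0, 5), latitude = c(55, 57))
  pa <- sample_pseudoabsences(env$grid, env, pres, 2000, 20,
                              variables = c("SSST", "SSIC"), seed = 1)
  tr <- build_training_set(env, pres, pa, c("SSST", "SSIC"))
  expect_setequal(unique(tr$label), c("presence", "pseudo_absence"))
  expect_false(anyNA(tr$SSST))
  expect_equal(nrow(tr), 22)
})
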