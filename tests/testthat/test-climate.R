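test_that("anomalies follow the centering identities and the warming flag", {
  g <- tiny_grid()
  env <- tiny_env(g, years = 2000:2009, ssst_trend = 0)
  a <- summer_anomaly(env, "SSST", climatology = "baseline")
  expect_true(all(abs(a$anomaly) < 1e-10))     # flat scenario: zero anomaly
  # first_k climatology over the whole record centers the series
  env2 <- tiny_env(g, years = 2000:2009, ssst_trend = 1)
  a2 <- summer_anomaly(env2, "SSST", climatology = "first_k", k = 10)
  for (r in unique(a2$region))
    expect_lt(abs(mean(a2$anomaly[a2$region == r])), 1e-10)
  # arithmetic + flag: +0.7 over climatology
  expect_true(all(a2$warming_flag == (a2$anomaly >= 0.5)))
  expect_error(summer_anomaly(env, "NOPE"), "unknown variable")
})

test_that("ice regimes use the anomaly sign rule and pooled intersections", {
  an <- data.frame(region = 1, year = 2001:2004,
                   anomaly = c(-1.2, 0.3, 2.0, -0.5))
  r <- classify_ice_regimes(an)
  expect_equal(r$per_region$regime, c("low", "high", "high", "low"))
  expect_equal(r$pooled_low, c(2001, 2004))
  expect_equal(r$pooled_high, c(2002, 2003))
  expect_warning(classify_ice_regimes(
    data.frame(region = 1, year = 2001:2003, anomaly = c(-1, -2, -3))),
    "empty")
  # two regions with opposite signs -> both pooled sets empty
  opp <- rbind(data.frame(region = 1, year = 2001:2004,
                          anomaly = c(-1, 1, -1, 1)),
               data.frame(region = 2, year = 2001:2004,
                          anomaly = c(1, -1, 1, -1)))
  expect_warning(ro <- classify_ice_regimes(opp), "empty")
  expect_length(ro$pooled_low, 0)
  # invariance to adding a constant to the underlying values is inherited
  # from anomaly centering: anomalies themselves are unchanged
  an2 <- an; an2$anomaly <- an$anomaly   # (already centered quantities)
  expect_identical(classify_ice_regimes(an2)$per_region$regime,
                   r$per_region$regime)
})

test_that("Mann-Kendall matches the stated formulas on derived cases", {
  mk <- mann_kendall(1:5)
  expect_equal(mk$S, 10)
  expect_equal(mk$var_S, 50 / 3, tolerance = 1e-12)
  expect_equal(mk$z, 9 / sqrt(50 / 3), tolerance = 1e-12)
  expect_equal(mk$sen_slope, 1)
  const <- mann_kendall(rep(2, 6))
  expect_equal(const$S, 0)
  expect_equal(const$z, 0)
  expect_equal(const$sen_slope, 0)
  dec <- mann_kendall(5:1)
  expect_equal(dec$S, -10)
  expect_equal(dec$z, -mk$z)
  expect_error(mann_kendall(1:3), "at least 4")
})

test_that("Mann-Kendall agrees with a brute-force oracle incl. ties", {
  brute <- function(x) {
    n <- length(x); S <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
    tt <- table(x)
    varS <- (n * (n - 1) * (2 * n + 5) -
               sum(tt * (tt - 1) * (2 * tt + 5))) / 18
    list(S = S, var_S = varS)
  }
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- if (i %% 2) rnorm(n) else sample(1:4, n, replace = TRUE)  # ties
    got <- mann_kendall(x)
    want <- brute(x)
    expect_identical(got$S, want$S)
    expect_equal(got$var_S, want$var_S, tolerance = 1e-12)
  }
  # noiseless linear trend: Sen slope exact
  expect_equal(mann_kendall(2 + 0.37 * (1:12))$sen_slope, 0.37,
               tolerance = 1e-12)
})

test_that("the pixel-wise map equals the scalar test per pixel", {
  set.seed(12)
  arr <- array(rnorm(4 * 5 * 8), c(4, 5, 8))
  arr[2, 2, ] <- round(arr[2, 2, ])          # force some ties
  years <- 2001:2008
  m <- mk_trend_map(arr, years)
  for (cell in list(c(1, 1), c(2, 2), c(4, 5))) {
    ref <- mann_kendall(arr[cell[1], cell[2], ], years)
    expect_equal(m$S[cell[1], cell[2]], ref$S)
    expect_equal(m$var_S[cell[1], cell[2]], ref$var_S, tolerance = 1e-12)
    expect_equal(m$p[cell[1], cell[2]], ref$p, tolerance = 1e-12)
    expect_equal(m$sen_slope[cell[1], cell[2]], ref$sen_slope,
                 tolerance = 1e-12)
  }
})

test_that("hotspots apply the >= 2-of-4 rule and overlap statistics", {
  dims <- c(2, 2)
  mkmap <- function(p, sen) structure(
    list(S = matrix(1, 2, 2), var_S = matrix(1, 2, 2), z = matrix(1, 2, 2),
         p = matrix(p, 2, 2), sen_slope = matrix(sen, 2, 2), n_years = 20),
    class = "arc_mk_map")
  # pixel-wise: SSST and SSIC large; SCHL/SZOOC not significant
  tm <- list(SSST = mkmap(0.01, 0.05),     # 0.5/decade inside [0.21, 0.76]
             SSIC = mkmap(0.01, -1),       # -10/decade inside [-76, -2]
             SCHL = mkmap(0.5, 0.05),
             SZOOC = mkmap(0.5, 0.05))
  hs <- hotspot_map(tm)
  expect_true(all(hs$hotspot))
  expect_equal(hs$n_large[1, 1], 2)
  # only one large change -> not a hotspot
  tm1 <- tm; tm1$SSIC <- mkmap(0.9, -1)
  expect_true(all(!hotspot_map(tm1)$hotspot))
  expect_error(hotspot_map(tm[1:3]), "missing trend map")
  # overlap: accrual identical to hotspot mask -> 100%
  g <- tiny_grid(n_regions = 1)
  mk_big <- function(p, sen) structure(
    list(p = matrix(p, g$n_rows, g$n_cols),
         sen_slope = matrix(sen, g$n_rows, g$n_cols)),
    class = "arc_mk_map")
  tmg <- list(SSST = mk_big(0.01, 0.05), SSIC = mk_big(0.01, -1),
              SCHL = mk_big(0.5, 0.05), SZOOC = mk_big(0.5, 0.05))
  hsg <- hotspot_map(tmg, accrual = matrix(TRUE, g$n_rows, g$n_cols),
                     grid = g)
  expect_equal(
    hsg$overlap$percent_accrual_overlap[hsg$overlap$mask == "hotspot"], 100)
})
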