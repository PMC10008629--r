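test_that("richness counts, zero-species map and guild additivity", {
  dims <- c(4, 6)
  st <- random_binary_stack(3, dims)
  st <- lapply(st, function(m) { m[1, 1] <- TRUE; m })   # all present at 1,1
  sr <- richness_stack(st)
  expect_equal(sr[1, 1], 3L)
  expect_equal(richness_stack(list(), dims = dims), matrix(0L, 4, 6))
  expect_error(richness_stack(list(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3))),
               "mixed grids")
  set.seed(3)
  apex <- random_binary_stack(2, dims)
  meso <- random_binary_stack(3, dims)
  expect_equal(richness_stack(c(apex, meso)),
               richness_stack(apex) + richness_stack(meso))
})

test_that("richness trends recover exact and noisy imposed slopes", {
  years <- 2000:2019
  # exact linear pixel: SR = 1..20 -> slope 1, p ~ 0
  maps <- lapply(seq_along(years), function(t) matrix(t, 2, 2))
  tr <- richness_trend(maps, years)
  expect_equal(tr$slope[1, 1], 1)
  expect_lt(tr$p[1, 1], 1e-10)
  flat <- richness_trend(lapply(years, function(y) matrix(5, 2, 2)), years)
  expect_equal(flat$slope[1, 1], 0)
  expect_error(richness_trend(maps[1:2], years[1:2]), "3 years")
  # parameter recovery: 0.15 species/year + N(0, 0.5), 20 reps
  set.seed(14)
  hits <- replicate(20, {
    y <- 3 + 0.15 * (years - 2000) + rnorm(20, 0, 0.5)
    f <- ols_trend(years, y)
    abs(f$slope - 0.15) <= 3 * f$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("accrual mask applies the >= 1 species/decade boundary rule", {
  slope <- matrix(c(0.1, 0.09, 0.2, -0.3), 2, 2)
  trend <- structure(list(slope = slope, p = slope * 0, n_years = 20),
                     class = "arc_trend_map")
  acc <- accrual_mask(trend, min_per_decade = 1)
  expect_true(acc$mask[1, 1])      # exactly 1/decade included
  expect_false(acc$mask[2, 1])     # 0.9/decade excluded
  expect_true(acc$mask[1, 2])
})

test_that("accrual series correlates exactly with a linear SST construction", {
  g <- tiny_grid(n_regions = 1)
  years <- 2000:2009
  # richness everywhere equals year index -> accrual everywhere, mean series
  # linear; SST anomaly series constructed as the same line
  maps <- lapply(seq_along(years), function(t)
    matrix(t, g$n_rows, g$n_cols))
  tr <- richness_trend(maps, years, g)
  anom <- data.frame(region = 1, year = years,
                     anomaly = 2 * seq_along(years) + 1)
  acc <- accrual_mask(tr, 1, g, maps, years, anom)
  expect_equal(acc$correlation$r[1], 1, tolerance = 1e-12)
  expect_equal(acc$region_freq$frequency, 1)
})

test_that("Sorensen partition matches the stated closed forms", {
  mk <- function(x) matrix(x, 1, 1)
  # identity: A = B non-empty
  A <- list(s1 = mk(TRUE), s2 = mk(TRUE), s3 = mk(FALSE))
  b <- beta_decompose(A, A)
  expect_equal(b$beta_sor[1, 1], 0)
  expect_equal(b$beta_sim[1, 1], 0)
  expect_equal(b$beta_sne[1, 1], 0)
  # nested: A = 4 species, B = 2 of them -> a=2, b=2, c=0
  A4 <- list(s1 = mk(TRUE), s2 = mk(TRUE), s3 = mk(TRUE), s4 = mk(TRUE))
  B2 <- list(s1 = mk(TRUE), s2 = mk(TRUE), s3 = mk(FALSE), s4 = mk(FALSE))
  nb <- beta_decompose(A4, B2)
  expect_equal(nb$beta_sor[1, 1], 1 / 3, tolerance = 1e-12)
  expect_equal(nb$beta_sim[1, 1], 0)
  expect_equal(nb$beta_sne[1, 1], 1 / 3, tolerance = 1e-12)
  # pure turnover: a = b = c = 1
  At <- list(s1 = mk(TRUE), s2 = mk(TRUE), s3 = mk(FALSE))
  Bt <- list(s1 = mk(TRUE), s2 = mk(FALSE), s3 = mk(TRUE))
  tb <- beta_decompose(At, Bt)
  expect_equal(tb$beta_sor[1, 1], 0.5)
  expect_equal(tb$beta_sim[1, 1], 0.5)
  expect_equal(tb$beta_sne[1, 1], 0)
  # both empty -> flagged undefined
  E <- list(s1 = mk(FALSE)); names(E) <- "s1"
  eb <- beta_decompose(E, E)
  expect_true(is.na(eb$beta_sor[1, 1]))
  names(E) <- "zz"
  expect_error(beta_decompose(A, E), "species lists differ")
})

test_that("range-size change does the stated set arithmetic", {
  # baseline 100 cells, comparison 120, overlap 90
  A <- matrix(FALSE, 20, 20); B <- matrix(FALSE, 20, 20)
  A[1:100] <- TRUE
  B[11:130] <- TRUE
  rc <- range_size_change(A, B)
  expect_equal(unname(rc$n["loss"]), 10)
  expect_equal(unname(rc$n["gain"]), 30)
  expect_equal(unname(rc$n["stable_present"]), 90)
  expect_equal(rc$direction, "accrual")
  expect_equal(unname(rc$pct_of_baseline["gain"]), 30)
  # identity and disjoint symmetry
  expect_equal(range_size_change(A, A)$direction, "unchanged")
  D <- matrix(FALSE, 20, 20); D[301:400] <- TRUE
  rd <- range_size_change(A, D)
  expect_equal(unname(rd$n["loss"]), unname(rd$n["gain"]))
  expect_equal(rd$direction, "unchanged")
  # the four categories partition all cells
  expect_equal(sum(rc$n), 400)
})

test_that("regime averaging uses the majority >= 0.5 rule", {
  m1 <- matrix(TRUE, 1, 1); m0 <- matrix(FALSE, 1, 1)
  bins <- list(`2000` = m1, `2001` = m1, `2002` = m1, `2003` = m0)
  expect_true(regime_average_binary(bins, 2000:2003)[1, 1])     # 3/4
  bins2 <- list(`2000` = m1, `2001` = m0, `2002` = m0, `2003` = m0)
  expect_false(regime_average_binary(bins2, 2000:2003)[1, 1])   # 1/4
  bins3 <- list(`2000` = m1, `2001` = m1, `2002` = m0, `2003` = m0)
  expect_true(regime_average_binary(bins3, 2000:2003)[1, 1])    # tie 2/4
  expect_error(regime_average_binary(bins, integer(0)), "non-empty")
  expect_error(regime_average_binary(bins, 1999), "missing")
})
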