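# Shared numerical utilities: seeding, great-circle distance, trend fits.

EARTH_RADIUS_KM <- 6371

#' Derive a named sub-seed from a master seed
#'
#' Every stochastic operation in the pipeline draws its own sub-seed from the
#' single master seed plus a stage name, so stages are individually
#' reproducible and reordering one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param name character tag of the consuming operation.
#' @return an integer in `[0, 2^31)`.
#' @export
sub_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(master) * 2654435769 + h) %% 2147483647)
}

#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371 km. Inputs are recycled;
#' coordinates are WGS84 decimal degrees.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Cross distance matrix (n1 x n2) in km; fine for the point-set sizes the
# thinning and buffering stages see (<= a few thousand points).
cross_dist_km <- function(lon1, lat1, lon2, lat2) {
  n1 <- length(lon1); n2 <- length(lon2)
  matrix(haversine_km(rep(lon1, times = n2), rep(lat1, times = n2),
                      rep(lon2, each = n1), rep(lat2, each = n1)),
         nrow = n1, ncol = n2)
}

#' Ordinary least-squares trend of a series on time
#'
#' @param x numeric predictor (typically calendar years).
#' @param y numeric response.
#' @return list with `slope`, `intercept`, `p` (two-sided on the slope),
#'   `r2`, `adj_r2`, `se` (slope standard error), `n`.
#' @export
ols_trend <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("ols_trend() needs at least 3 complete observations")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - my)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  p <- if (se == 0) as.numeric(slope != 0) * 0 else
    2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  r2 <- if (sst == 0) NA_real_ else 1 - sse / sst
  adj <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - 2)
  list(slope = slope, intercept = intercept, p = p,
       r2 = r2, adj_r2 = adj, se = se, n = n)
}

# Pearson correlation that degrades to NA (not an error) on zero variance.
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Per-pixel OLS slope/p across the third dimension of an array, vectorised.
# `values` is cells x years; returns list of vectors.
rowwise_ols <- function(values, years) {
  n <- length(years)
  stopifnot(ncol(values) == n, n >= 3)
  x <- years - mean(years)
  sxx <- sum(x^2)
  ym <- rowMeans(values)
  slope <- as.vector(values %*% x) / sxx
  fitted_dev <- outer(slope, x)
  res <- values - ym - fitted_dev
  sse <- rowSums(res^2)
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(slope = slope, p = p, se = se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
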