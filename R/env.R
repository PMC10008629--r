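# Synthetic multi-year summer environment: warming, sea-ice decline,
# productivity, and the derived distance-to-ice-edge covariate.

ENV_DYNAMIC_VARS <- c("SSST", "SSIC", "SCHL", "SZOOC", "salinity")
ENV_STATIC_VARS <- c("depth", "dist_coast")
ENV_ALL_VARS <- c(ENV_DYNAMIC_VARS, ENV_STATIC_VARS, "dist_ice_edge")

#' Default environmental scenario
#'
#' Baseline fields, decadal trends and noise levels for the synthetic summer
#' environment. The dynamic variables are summer sea surface temperature
#' (SSST, deg C), summer sea ice concentration (SSIC, percent), summer
#' chlorophyll-a (SCHL, mg m-3), summer zooplankton biomass (SZOOC, g m-2)
#' and salinity (PSU). Baselines follow a latitudinal gradient (warm/ice-free
#' in the south); trends impose warming (+0.3 C/decade), ice loss
#' (-8 %/decade) and increasing productivity, magnitudes sitting inside the
#' decadal-change bounds the hotspot stage screens for.
#'
#' @param grid an `arc_grid`.
#' @return named list of per-variable specs
#'   (`baseline` matrix, `trend_per_decade`, `noise_sd`, `interannual_sd`,
#'   `min`, `max`).
#' @export
default_trend_spec <- function(grid) {
  lat <- matrix(rep(grid$lat_centers, grid$n_cols), grid$n_rows, grid$n_cols)
  list(
    SSST = list(baseline = 12 - 0.28 * (lat - 50), trend_per_decade = 0.3,
                noise_sd = 0.3, interannual_sd = 0.4, min = -Inf, max = Inf),
    SSIC = list(baseline = pmax(0, pmin(95, (lat - 62) * 3.2)),
                trend_per_decade = -8,
                noise_sd = 3, interannual_sd = 5, min = 0, max = 100),
    SCHL = list(baseline = pmax(0.05, 2.2 - 0.05 * (lat - 50)),
                trend_per_decade = 0.4,
                noise_sd = 0.1, interannual_sd = 0.1, min = 0, max = Inf),
    SZOOC = list(baseline = pmax(0.5, 8 - 0.15 * (lat - 50)),
                 trend_per_decade = 0.4,
                 noise_sd = 0.15, interannual_sd = 0.1, min = 0, max = Inf),
    salinity = list(baseline = 32 + 0.05 * (lat - 50), trend_per_decade = 0,
                    noise_sd = 0.1, interannual_sd = 0.2,
                    min = -Inf, max = Inf)
  )
}

#' Simulate the multi-year environmental stack
#'
#' Each dynamic variable is `baseline + trend + interannual anomaly + pixel
#' noise`, clipped to its physical range. Depth and distance-to-coast are
#' static; distance to the summer sea-ice edge is recomputed every year as
#' the shortest great-circle distance to the 15 percent sea-ice-concentration
#' contour. Degenerate years follow a fixed rule: an all-ice year has
#' distance 0 everywhere, an ice-free year uses the distance to the northern
#' domain edge, so the covariate stays totally ordered with no undefined
#' cells.
#'
#' @param grid an `arc_grid`.
#' @param years integer vector of calendar years (>= 2).
#' @param trend_spec per-variable scenario, see [default_trend_spec()].
#' @param seed integer master seed.
#' @return an `arc_env`: `grid`, `years`, `layers` (named list of
#'   `n_rows x n_cols x n_years` arrays), and `truth` recording the imposed
#'   per-year trends and baselines.
#' @export
simulate_environment <- function(grid, years, trend_spec = default_trend_spec(grid),
                                 seed = 1) {
  stopifnot(inherits(grid, "arc_grid"))
  if (length(years) < 2) stop("need at least 2 years")
  unknown <- setdiff(names(trend_spec), ENV_DYNAMIC_VARS)
  if (length(unknown))
    stop("trend_spec names unknown variable(s): ", paste(unknown, collapse = ", "))
  ny <- length(years)
  dims <- c(grid$n_rows, grid$n_cols, ny)
  layers <- list()
  truth <- list(trend_per_year = list(), baseline = list())

  for (v in names(trend_spec)) {
    sp <- trend_spec[[v]]
    set.seed(sub_seed(seed, paste0("env_", v)))
    inter <- stats::rnorm(ny, 0, sp$interannual_sd)
    arr <- array(NA_real_, dims)
    for (t in seq_len(ny)) {
      noise <- if (sp$noise_sd > 0)
        matrix(stats::rnorm(grid$n_rows * grid$n_cols, 0, sp$noise_sd),
               grid$n_rows, grid$n_cols) else 0
      val <- sp$baseline + sp$trend_per_decade / 10 * (years[t] - years[1]) +
        inter[t] + noise
      arr[, , t] <- pmin(pmax(val, sp$min), sp$max)
    }
    layers[[v]] <- arr
    truth$trend_per_year[[v]] <- sp$trend_per_decade / 10
    truth$baseline[[v]] <- sp$baseline
  }

  lat <- matrix(rep(grid$lat_centers, grid$n_cols), grid$n_rows, grid$n_cols)
  set.seed(sub_seed(seed, "env_depth"))
  depth <- pmin(-5, -(40 + 70 * (lat - 50)) +
                  matrix(stats::rnorm(grid$n_rows * grid$n_cols, 0, 150),
                         grid$n_rows, grid$n_cols))
  layers$depth <- array(rep(depth, ny), dims)
  dc <- dist_to_coast(grid)
  layers$dist_coast <- array(rep(dc, ny), dims)

  if (!is.null(layers$SSIC)) {
    die <- array(NA_real_, dims)
    for (t in seq_len(ny)) die[, , t] <- ice_edge_distance(grid, layers$SSIC[, , t])
    layers$dist_ice_edge <- die
  }

  structure(list(grid = grid, years = as.integer(years),
                 layers = layers, truth = truth),
            class = "arc_env")
}

#' Extract one raster layer from an environmental stack
#'
#' @param env an `arc_env`.
#' @param variable variable name.
#' @param year calendar year present in `env$years`.
#' @return `n_rows x n_cols` matrix.
#' @export
env_layer <- function(env, variable, year) {
  if (!variable %in% names(env$layers)) stop("unknown variable: ", variable)
  t <- match(year, env$years)
  if (is.na(t)) stop("year ", year, " not in stack")
  env$layers[[variable]][, , t]
}

# Shortest great-circle distance (km) from every cell to the 15% sea-ice
# contour, taken as the set of icy cells (SSIC >= 15) that border a non-icy
# cell; those contour cells get distance exactly 0.
ice_edge_distance <- function(grid, ssic, threshold = 15) {
  icy <- ssic >= threshold
  nr <- nrow(ssic); nc <- ncol(ssic)
  if (all(icy)) return(matrix(0, nr, nc))
  if (!any(icy)) {
    # ice-free fallback: distance to the northern domain edge
    north <- grid$lat_centers[nr] + grid$cell_size_deg / 2
    d <- haversine_km(0, grid$lat_centers, 0, north)
    return(matrix(rep(d, nc), nr, nc))
  }
  # 4-neighbour shift comparison (longitude wraps, latitude does not)
  up <- rbind(icy[-1, , drop = FALSE], icy[nr, , drop = FALSE])
  down <- rbind(icy[1, , drop = FALSE], icy[-nr, , drop = FALSE])
  left <- cbind(icy[, nc, drop = FALSE], icy[, -nc, drop = FALSE])
  right <- cbind(icy[, -1, drop = FALSE], icy[, 1, drop = FALSE])
  edge <- icy & !(up & down & left & right)
  cc <- cell_coords(grid)
  ei <- which(as.vector(edge))
  elon <- cc$lon[ei]; elat <- cc$lat[ei]
  out <- numeric(nr * nc)
  chunk <- max(1L, floor(2e6 / length(ei)))
  idx <- seq_len(nr * nc)
  for (s in split(idx, ceiling(idx / chunk))) {
    d <- cross_dist_km(cc$lon[s], cc$lat[s], elon, elat)
    out[s] <- apply(d, 1, min)
  }
  out[as.vector(edge)] <- 0
  matrix(out, nr, nc)
}

# Static distance-to-coast field (km to the nearest land cell); Inf when the
# grid has no land.
dist_to_coast <- function(grid) {
  cc <- cell_coords(grid)
  li <- which(as.vector(grid$land_mask))
  nr <- grid$n_rows; nc <- grid$n_cols
  if (!length(li)) return(matrix(Inf, nr, nc))
  out <- numeric(nr * nc)
  idx <- seq_len(nr * nc)
  chunk <- max(1L, floor(2e6 / length(li)))
  for (s in split(idx, ceiling(idx / chunk))) {
    d <- cross_dist_km(cc$lon[s], cc$lat[s], cc$lon[li], cc$lat[li])
    out[s] <- apply(d, 1, min)
  }
  matrix(out, nr, nc)
}

#' Write an environmental stack as long-format CSV
#'
#' One row per (variable, year, cell): `variable,year,lat,lon,value`.
#' A plain-text stand-in for a NetCDF stack with year/lat/lon dimensions.
#'
#' @param env an `arc_env`.
#' @param path output file.
#' @param variables subset of variables (default all).
#' @export
write_env_csv <- function(env, path, variables = names(env$layers)) {
  cc <- cell_coords(env$grid)
  rows <- lapply(variables, function(v) {
    do.call(rbind, lapply(seq_along(env$years), function(t) {
      data.frame(variable = v, year = env$years[t],
                 lat = cc$lat, lon = cc$lon,
                 value = as.vector(env$layers[[v]][, , t]))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
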