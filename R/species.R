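# Virtual species: Gaussian-product niches, prevalence-thresholded truth
# occupancy with a mobility-capped poleward front, and biased presence-only
# sampling.

#' Define a virtual species
#'
#' The suitability model is a product of per-variable Gaussian responses
#' `exp(-0.5 * ((x - optimum) / breadth)^2)`, so suitability is 1 when every
#' covariate sits at its optimum. Guild defaults mimic wide-ranging apex
#' predators (broader thermal breadth, higher poleward mobility) versus more
#' sedentary mesopredators.
#'
#' @param species_id identifier string.
#' @param guild `"apex"` or `"meso"`.
#' @param niche_spec named list, one entry per covariate:
#'   `c(optimum, breadth)` in the covariate's units; breadth > 0.
#' @param prevalence_target fraction of in-region ocean cells occupied.
#' @param allowed_regions integer region ids the species may occupy.
#' @param mobility_km_per_year cap on poleward range-front displacement;
#'   `NULL` picks the guild default (150 apex, 50 meso).
#' @return object of class `arc_species`.
#' @export
define_virtual_species <- function(species_id, guild = c("apex", "meso"),
                                   niche_spec,
                                   prevalence_target = 0.15,
                                   allowed_regions = 1:8,
                                   mobility_km_per_year = NULL) {
  guild <- match.arg(guild)
  if (length(niche_spec) == 0) stop("niche_spec must name at least one variable")
  for (v in names(niche_spec)) {
    if (length(niche_spec[[v]]) != 2 || niche_spec[[v]][2] <= 0)
      stop("niche_spec[['", v, "']] must be c(optimum, breadth) with breadth > 0")
  }
  if (length(allowed_regions) == 0) stop("allowed_regions must be non-empty")
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0,1)")
  mob <- mobility_km_per_year %||% if (guild == "apex") 150 else 50
  structure(list(species_id = species_id, guild = guild,
                 niche = niche_spec,
                 prevalence_target = prevalence_target,
                 allowed_regions = as.integer(allowed_regions),
                 mobility_km_per_year = mob),
            class = "arc_species")
}

#' Default virtual community
#'
#' Twelve species by default (4 apex, 8 meso), echoing the apex/mesopredator
#' split of the modelled Arctic taxa at desk scale. Thermal optima are drawn
#' from the realized first-year temperature field; apex species get wider
#' thermal breadth, full regional extent and higher mobility, mesopredators
#' narrower niches and a contiguous subset of regions. Half of each guild
#' also carries a sea-ice response (ice-associated or open-water).
#'
#' @param env an `arc_env` (first year defines realized covariate ranges).
#' @param n_apex,n_meso guild sizes.
#' @param seed integer seed.
#' @return list of `arc_species`.
#' @export
default_species_set <- function(env, n_apex = 4, n_meso = 8, seed = 1) {
  set.seed(sub_seed(seed, "species_set"))
  grid <- env$grid
  oc <- ocean_mask(grid)
  sst1 <- env_layer(env, "SSST", env$years[1])[oc]
  qs <- stats::quantile(sst1, c(0.25, 0.85))
  regions <- sort(setdiff(unique(as.vector(grid$region_id)), 0L))
  out <- list()
  n <- n_apex + n_meso
  for (i in seq_len(n)) {
    apex <- i <= n_apex
    guild <- if (apex) "apex" else "meso"
    opt <- stats::runif(1, qs[1], qs[2])
    breadth <- if (apex) stats::runif(1, 2.5, 3.5) else stats::runif(1, 1.2, 2)
    niche <- list(SSST = c(opt, breadth))
    if (i %% 2 == 0) { # ice-associated vs open-water split
      ice_opt <- if (stats::runif(1) < 0.5) 0 else 60
      niche$SSIC <- c(ice_opt, if (apex) 45 else 30)
    }
    niche$depth <- c(stats::runif(1, -2500, -200), 1800)
    allowed <- if (apex) regions else {
      k <- sample(3:min(6, length(regions)), 1)
      start <- sample(seq_along(regions), 1)
      regions[((start + seq_len(k) - 2) %% length(regions)) + 1]
    }
    out[[i]] <- define_virtual_species(
      species_id = sprintf("sp%02d_%s", i, guild), guild = guild,
      niche_spec = niche,
      prevalence_target = stats::runif(1, 0.10, 0.25),
      allowed_regions = allowed)
  }
  out
}

#' Habitat suitability map
#'
#' Pure function of the species' niche and the year's covariate layers;
#' values in `[0, 1]`.
#'
#' @param species an `arc_species`.
#' @param env an `arc_env`.
#' @param year calendar year.
#' @return `n_rows x n_cols` matrix in `[0,1]`.
#' @export
suitability_map <- function(species, env, year) {
  s <- 1
  for (v in names(species$niche)) {
    par <- species$niche[[v]]
    x <- env_layer(env, v, year)
    s <- s * exp(-0.5 * ((x - par[1]) / par[2])^2)
  }
  if (!is.matrix(s)) s <- matrix(s, env$grid$n_rows, env$grid$n_cols)
  s
}

#' Truth occupancy map
#'
#' Suitability thresholded at the quantile achieving the species'
#' prevalence target among in-region ocean cells (standard virtual-ecologist
#' practice, so the true range is known exactly). The poleward range front
#' may advance at most `mobility_km_per_year` from its first-year position,
#' capping how fast warming can drag the range north.
#'
#' @param species an `arc_species`.
#' @param env an `arc_env`.
#' @param year calendar year.
#' @return logical `n_rows x n_cols` matrix.
#' @export
occupancy_map <- function(species, env, year) {
  grid <- env$grid
  mask <- ocean_mask(grid) &
    matrix(grid$region_id %in% species$allowed_regions,
           grid$n_rows, grid$n_cols)
  occ_at <- function(yr) {
    suit <- suitability_map(species, env, yr)
    vals <- suit[mask]
    thr <- stats::quantile(vals, 1 - species$prevalence_target, names = FALSE)
    suit >= thr & mask
  }
  occ <- occ_at(year)
  y0 <- env$years[1]
  if (year > y0) {
    occ0 <- occ_at(y0)
    if (any(occ0)) {
      lat <- matrix(rep(grid$lat_centers, grid$n_cols),
                    grid$n_rows, grid$n_cols)
      front0 <- max(lat[occ0])
      # km -> degrees latitude on the 6371-km sphere
      cap <- front0 + species$mobility_km_per_year * (year - y0) /
        (pi * EARTH_RADIUS_KM / 180)
      occ[lat > cap] <- FALSE
    }
  }
  occ
}

#' Sample biased presence-only occurrences
#'
#' Presence cells are drawn with probability proportional to
#' `suitability x occupancy x bias`; each record is jittered uniformly
#' within its cell, emulating spatially biased archive/trawl sampling.
#' The default bias decays with distance to the coast (e-folding 300 km).
#'
#' @param species an `arc_species`.
#' @param env an `arc_env`.
#' @param year calendar year.
#' @param n_samples number of records to draw (>= 1).
#' @param bias_field non-negative `n_rows x n_cols` matrix, or `NULL` for
#'   the coastal-effort default.
#' @param seed integer seed.
#' @return list with `occurrences` (data.frame
#'   `species_id,guild,longitude,latitude,year,source`) and `occupancy`
#'   (the truth map used).
#' @export
sample_occurrences <- function(species, env, year, n_samples,
                               bias_field = NULL, seed = 1) {
  stopifnot(n_samples >= 1)
  grid <- env$grid
  if (is.null(bias_field))
    bias_field <- exp(-env_layer(env, "dist_coast", year) / 300)
  if (any(bias_field < 0)) stop("bias_field must be non-negative")
  occ <- occupancy_map(species, env, year)
  w <- suitability_map(species, env, year) * occ * bias_field
  if (!any(w > 0)) stop("no samplable cells: all sampling weights are zero")
  set.seed(sub_seed(seed, paste0("occ_", species$species_id, "_", year)))
  cells <- sample.int(length(w), n_samples, replace = TRUE, prob = as.vector(w))
  cc <- cell_coords(grid)
  half <- grid$cell_size_deg / 2
  jit_lon <- stats::runif(n_samples, -half, half)
  jit_lat <- stats::runif(n_samples, -half, half)
  list(
    occurrences = data.frame(
      species_id = species$species_id, guild = species$guild,
      longitude = cc$lon[cells] + jit_lon,
      latitude = cc$lat[cells] + jit_lat,
      year = as.integer(year), source = "synthetic",
      stringsAsFactors = FALSE),
    occupancy = occ)
}
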