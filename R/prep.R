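# Occurrence cleaning, spatial thinning, environmental profiling and
# two-round pseudo-absence sampling.

#' Clean an occurrence table
#'
#' Keeps at-sea records inside the grid bounds and removes exact coordinate
#' duplicates within each species-year.
#'
#' @param raw data.frame with `species_id, longitude, latitude, year`
#'   (extra columns pass through).
#' @param grid an `arc_grid`.
#' @return the cleaned data.frame; attribute `"log"` records row counts.
#' @export
clean_occurrences <- function(raw, grid) {
  n0 <- nrow(raw)
  if (n0 == 0) return(raw)
  cells <- coord_to_cell(grid, raw$longitude, raw$latitude)
  inside <- !is.na(cells$index)
  at_sea <- inside
  at_sea[inside] <- as.vector(ocean_mask(grid))[cells$index[inside]]
  out <- raw[at_sea, , drop = FALSE]
  dup <- duplicated(out[, c("species_id", "year", "longitude", "latitude")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- c(input = n0, outside = sum(!inside),
                        on_land = sum(inside) - sum(at_sea),
                        duplicates = sum(dup), retained = nrow(out))
  out
}

#' Spatially thin occurrences to a minimum nearest-neighbour distance
#'
#' Within each species-year, records are iteratively deleted (the record with
#' the most neighbours closer than `thin_km` goes first, ties broken at
#' random) until no pair is closer than `thin_km` great-circle distance.
#' The procedure is randomized and repeated `n_reps` times; the run
#' retaining the most records wins. Thinning an already-thinned set is a
#' no-op.
#'
#' @param occ cleaned occurrence data.frame.
#' @param thin_km minimum allowed pairwise distance (default 100 km, the
#'   threshold that best controlled spatial sampling bias in the source
#'   analysis).
#' @param n_reps randomized repetitions (default 10).
#' @param seed integer seed.
#' @return thinned data.frame; attribute `"log"` records before/after counts.
#' @export
thin_occurrences <- function(occ, thin_km = 100, n_reps = 10, seed = 1) {
  if (thin_km <= 0) stop("thin_km must be positive")
  if (nrow(occ) == 0) return(occ)
  set.seed(sub_seed(seed, "thin"))
  groups <- split(seq_len(nrow(occ)),
                  paste(occ$species_id, occ$year, sep = "\r"))
  keep_all <- logical(nrow(occ))
  for (g in groups) {
    if (length(g) == 1) { keep_all[g] <- TRUE; next }
    d <- cross_dist_km(occ$longitude[g], occ$latitude[g],
                       occ$longitude[g], occ$latitude[g])
    close <- d < thin_km
    diag(close) <- FALSE
    best <- NULL
    for (rep in seq_len(n_reps)) {
      alive <- rep(TRUE, length(g))
      cnt <- rowSums(close)
      while (TRUE) {
        cnt_alive <- ifelse(alive, cnt, -1L)
        mx <- max(cnt_alive)
        if (mx <= 0) break
        cand <- which(cnt_alive == mx)
        drop <- if (length(cand) == 1) cand else sample(cand, 1)
        alive[drop] <- FALSE
        nb <- which(close[drop, ] & alive)
        cnt[nb] <- cnt[nb] - 1L
        cnt[drop] <- 0L
      }
      if (is.null(best) || sum(alive) > sum(best)) best <- alive
    }
    keep_all[g[best]] <- TRUE
  }
  out <- occ[keep_all, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- c(input = nrow(occ), retained = nrow(out),
                        thin_km = thin_km, n_reps = n_reps)
  out
}

#' Extract covariate values at point locations
#'
#' @param env an `arc_env`.
#' @param points data.frame with `longitude`, `latitude`, `year`.
#' @param variables covariate names.
#' @return data.frame of covariate columns aligned with `points` rows
#'   (NA outside the grid).
#' @export
extract_covariates <- function(env, points, variables) {
  cells <- coord_to_cell(env$grid, points$longitude, points$latitude)
  out <- as.data.frame(lapply(variables, function(v) {
    arr <- env$layers[[v]]
    if (is.null(arr)) stop("unknown variable: ", v)
    t <- match(points$year, env$years)
    vals <- rep(NA_real_, nrow(points))
    ok <- !is.na(cells$index) & !is.na(t)
    flat <- cells$index[ok] + (t[ok] - 1L) * env$grid$n_rows * env$grid$n_cols
    vals[ok] <- arr[flat]
    vals
  }))
  names(out) <- variables
  out
}

#' Environmental profile of a species' occupied covariate ranges
#'
#' Per-variable `[min, max]` over all pooled presence rows; used to exclude
#' environmentally similar pixels when drawing profiled pseudo-absences.
#'
#' @param presences data.frame of presence rows carrying the covariate
#'   columns.
#' @param variables covariate names to profile.
#' @return named list `variable -> c(min, max)`.
#' @export
build_env_profile <- function(presences, variables) {
  if (nrow(presences) == 0) stop("cannot build a profile from zero presences")
  prof <- lapply(variables, function(v) {
    x <- presences[[v]]
    if (is.null(x)) stop("presences lack covariate column: ", v)
    x <- x[is.finite(x)]
    if (!length(x)) stop("no finite values for variable: ", v)
    range(x)
  })
  names(prof) <- variables
  prof
}

#' Draw pseudo-absences for one species-year
#'
#' Candidate positions are ocean cell centers, excluding every cell within
#' `buffer_km` of that year's presences. In `"profiled"` mode, cells whose
#' covariates fall inside the occupied range on every profiled variable are
#' additionally excluded (a cell stays eligible if at least one profiled
#' variable lies outside its occupied range). Cells are sampled without
#' replacement; if the eligible pool is smaller than `n_target` the whole
#' pool is returned with a warning.
#'
#' @param grid an `arc_grid`.
#' @param env an `arc_env`.
#' @param presences presence data.frame (filtered to `species_id`; the year
#'   filter is applied here).
#' @param year calendar year.
#' @param n_target pseudo-absences requested (study default 10000/year;
#'   synthetic desk default 500/year).
#' @param buffer_km presence exclusion radius (default 100).
#' @param mode `"random"` (first round) or `"profiled"` (second round).
#' @param profile output of [build_env_profile()] (profiled mode only).
#' @param variables covariate columns to attach to the returned rows.
#' @param profile_rule `"any_outside"` (default: eligible if >= 1 profiled
#'   variable is outside the occupied range) or `"all_outside"`.
#' @param seed integer seed.
#' @return data.frame `species_id, year, longitude, latitude, label` plus
#'   covariates.
#' @export
sample_pseudoabsences <- function(grid, env, presences, year, n_target,
                                  buffer_km = 100,
                                  mode = c("random", "profiled"),
                                  profile = NULL,
                                  variables = ENV_ALL_VARS,
                                  profile_rule = c("any_outside", "all_outside"),
                                  seed = 1) {
  mode <- match.arg(mode)
  profile_rule <- match.arg(profile_rule)
  if (mode == "profiled" && is.null(profile))
    stop("profiled mode requires a profile")
  pres_y <- presences[presences$year == year, , drop = FALSE]
  cc <- cell_coords(grid)
  eligible <- as.vector(ocean_mask(grid))
  if (nrow(pres_y) > 0 && buffer_km > 0) {
    # only cells inside each presence's bounding box can be within the
    # buffer; exact haversine check on those candidates
    deg_per_km <- 180 / (pi * EARTH_RADIUS_KM)
    dlat <- buffer_km * deg_per_km
    for (i in seq_len(nrow(pres_y))) {
      plon <- pres_y$longitude[i]; plat <- pres_y$latitude[i]
      dlon <- min(180, dlat / max(cos(plat * pi / 180), 1e-6))
      rows <- which(abs(grid$lat_centers - plat) <= dlat + grid$cell_size_deg)
      lond <- abs(((grid$lon_centers - plon + 180) %% 360) - 180)
      cols <- which(lond <= dlon + grid$cell_size_deg)
      if (!length(rows) || !length(cols)) next
      cand <- as.vector(outer(rows, (cols - 1L) * grid$n_rows, "+"))
      cand <- cand[eligible[cand]]
      if (!length(cand)) next
      d <- haversine_km(cc$lon[cand], cc$lat[cand], plon, plat)
      eligible[cand[d <= buffer_km]] <- FALSE
    }
  }
  if (mode == "profiled") {
    idx <- which(eligible)
    pts <- data.frame(longitude = cc$lon[idx], latitude = cc$lat[idx],
                      year = year)
    cov <- extract_covariates(env, pts, names(profile))
    outside <- vapply(names(profile), function(v)
      cov[[v]] < profile[[v]][1] | cov[[v]] > profile[[v]][2],
      logical(nrow(cov)))
    if (!is.matrix(outside)) outside <- matrix(outside, nrow = nrow(cov))
    ok <- if (profile_rule == "any_outside") rowSums(outside) >= 1
          else rowSums(outside) == ncol(outside)
    eligible[idx[!ok]] <- FALSE
  }
  pool <- which(eligible)
  if (!length(pool)) stop("no eligible cells for pseudo-absence sampling")
  n_take <- min(n_target, length(pool))
  if (n_take < n_target)
    warning(sprintf("eligible pool (%d) smaller than n_target (%d); returning pool size",
                    length(pool), n_target))
  sp_id <- if (nrow(presences) > 0) presences$species_id[1] else NA_character_
  set.seed(sub_seed(seed, paste0("pa_", sp_id, "_", year, "_", mode)))
  take <- if (n_take == length(pool)) pool else sample(pool, n_take)
  out <- data.frame(species_id = sp_id, year = as.integer(year),
                    longitude = cc$lon[take], latitude = cc$lat[take],
                    label = "pseudo_absence", stringsAsFactors = FALSE)
  cbind(out, extract_covariates(env, out, variables))
}

#' Assemble a presence/pseudo-absence training set
#'
#' Attaches covariates to presences, labels rows, binds the pseudo-absences
#' and drops rows with missing covariates.
#'
#' @param env an `arc_env`.
#' @param presences cleaned, thinned presence data.frame.
#' @param pseudo_absences rows from [sample_pseudoabsences()] (possibly
#'   several years bound together).
#' @param variables covariate columns to include.
#' @return data.frame `species_id, year, longitude, latitude, label, <vars>`.
#' @export
build_training_set <- function(env, presences, pseudo_absences, variables) {
  pres <- data.frame(species_id = presences$species_id,
                     year = as.integer(presences$year),
                     longitude = presences$longitude,
                     latitude = presences$latitude,
                     label = "presence", stringsAsFactors = FALSE)
  pres <- cbind(pres, extract_covariates(env, pres, variables))
  cols <- c("species_id", "year", "longitude", "latitude", "label", variables)
  out <- rbind(pres[, cols], pseudo_absences[, cols])
  complete <- stats::complete.cases(out[, variables, drop = FALSE])
  if (any(!complete))
    warning(sum(!complete), " rows dropped for missing covariates")
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  out
}
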