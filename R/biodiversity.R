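# Richness maps and trends, species-accrual detection, Sorensen
# beta-diversity partition, and regime-contrast range-size change.

#' Stack per-species binary maps into a species-richness raster
#'
#' @param binaries named list of logical/0-1 matrices (one per species) on a
#'   common grid.
#' @param dims matrix dimensions, required only when `binaries` is empty
#'   (the zero-species richness map is all zeros).
#' @return integer matrix `SR` = per-pixel count of present species.
#' @export
richness_stack <- function(binaries, dims = NULL) {
  if (!length(binaries)) {
    if (is.null(dims)) stop("empty stack needs explicit dims")
    return(matrix(0L, dims[1], dims[2]))
  }
  dims <- lapply(binaries, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("binary maps are on mixed grids")
  sr <- Reduce(`+`, lapply(binaries, function(m) m * 1L))
  storage.mode(sr) <- "integer"
  sr
}

#' Per-pixel richness trend and regional trend table
#'
#' Ordinary least squares of richness on calendar year, per pixel
#' (complete-case: every supplied year contributes). With a grid, regional
#' mean-richness series are also fit, giving the per-region slope/decade,
#' two-sided p and adjusted R-squared table.
#'
#' @param richness_by_year list of richness matrices, one per year, in year
#'   order.
#' @param years calendar years (length >= 3).
#' @param grid optional `arc_grid` for the regional table.
#' @return an `arc_trend_map`: `slope` (species/year), `p`, `n_years`
#'   matrices-and-scalar, plus `regional` (data.frame
#'   `region, slope_per_decade, p, adj_R2`) when `grid` is given.
#' @export
richness_trend <- function(richness_by_year, years, grid = NULL) {
  if (length(years) < 3) stop("need at least 3 years for a trend")
  stopifnot(length(richness_by_year) == length(years))
  dims <- dim(richness_by_year[[1]])
  vals <- vapply(richness_by_year, as.vector, numeric(prod(dims)))
  fit <- rowwise_ols(vals, years)
  out <- list(slope = matrix(fit$slope, dims[1], dims[2]),
              p = matrix(fit$p, dims[1], dims[2]),
              n_years = length(years))
  if (!is.null(grid)) {
    regions <- sort(setdiff(unique(as.vector(grid$region_id)), 0L))
    out$regional <- do.call(rbind, lapply(regions, function(r) {
      inr <- grid$region_id == r & !grid$land_mask
      series <- vapply(richness_by_year, function(m) mean(m[inr]), numeric(1))
      tr <- ols_trend(years, series)
      data.frame(region = r, slope_per_decade = tr$slope * 10,
                 p = tr$p, adj_R2 = tr$adj_r2)
    }))
  }
  structure(out, class = "arc_trend_map")
}

#' Areas of species accrual
#'
#' Pixels whose richness trend reaches `min_per_decade` species per decade
#' (boundary included). Also returns per-region accrual cell frequencies
#' and, when annual richness maps are supplied, the annual regional
#' mean-richness-within-accrual series (the Hovmoeller data table) with a
#' Pearson correlation against a regional summer temperature anomaly series
#' when one is provided.
#'
#' @param trend an `arc_trend_map`.
#' @param min_per_decade accrual threshold (default 1 species/decade).
#' @param grid optional `arc_grid` for regional summaries.
#' @param richness_by_year,years optional annual richness maps for the
#'   accrual series.
#' @param sst_anomaly optional data.frame `region, year, anomaly`.
#' @return list with `mask` (logical matrix), `region_freq`
#'   (`region, n_accrual, n_cells, frequency`), `series`
#'   (`region, year, mean_SR_accrual`), `correlation`
#'   (`region, r, p`).
#' @export
accrual_mask <- function(trend, min_per_decade = 1, grid = NULL,
                         richness_by_year = NULL, years = NULL,
                         sst_anomaly = NULL) {
  mask <- trend$slope * 10 >= min_per_decade
  out <- list(mask = mask)
  if (!is.null(grid)) {
    regions <- sort(setdiff(unique(as.vector(grid$region_id)), 0L))
    out$region_freq <- do.call(rbind, lapply(regions, function(r) {
      inr <- grid$region_id == r & !grid$land_mask
      data.frame(region = r, n_accrual = sum(mask & inr), n_cells = sum(inr),
                 frequency = sum(mask & inr) / sum(inr))
    }))
    if (!is.null(richness_by_year)) {
      rows <- list()
      for (r in regions) {
        sel <- mask & grid$region_id == r & !grid$land_mask
        for (t in seq_along(years)) {
          rows[[length(rows) + 1L]] <- data.frame(
            region = r, year = years[t],
            mean_SR_accrual = if (any(sel))
              mean(richness_by_year[[t]][sel]) else NA_real_)
        }
      }
      out$series <- do.call(rbind, rows)
      if (!is.null(sst_anomaly)) {
        out$correlation <- do.call(rbind, lapply(regions, function(r) {
          s <- out$series[out$series$region == r, ]
          a <- sst_anomaly[sst_anomaly$region == r, ]
          m <- merge(s, a[, c("year", "anomaly")], by = "year")
          ct <- safe_cor(m$mean_SR_accrual, m$anomaly)
          data.frame(region = r, r = ct$r, p = ct$p)
        }))
      }
    }
  }
  out
}

#' Pairwise Sorensen beta-diversity partition
#'
#' Per pixel, with `a` shared species, `b` present only in community A and
#' `c` only in B: `beta_sor = (b + c) / (2a + b + c)` splits exactly into a
#' turnover component `beta_sim = min(b, c) / (a + min(b, c))` (species
#' replacement) and a nestedness component `beta_sne = beta_sor - beta_sim`
#' (loss without replacement). Pixels empty in both communities are NA.
#'
#' @param community_A,community_B named lists of logical matrices, same
#'   species names in the same order.
#' @return list of matrices `beta_sor`, `beta_sim`, `beta_sne`.
#' @export
beta_decompose <- function(community_A, community_B) {
  if (!identical(names(community_A), names(community_B)))
    stop("species lists differ between the two communities")
  dims <- dim(community_A[[1]])
  A <- vapply(community_A, as.vector, numeric(prod(dims)))
  B <- vapply(community_B, as.vector, numeric(prod(dims)))
  if (!is.matrix(A)) A <- matrix(A, nrow = prod(dims))
  if (!is.matrix(B)) B <- matrix(B, nrow = prod(dims))
  a <- rowSums(A * B)
  b <- rowSums(A * (1 - B))
  cc_ <- rowSums((1 - A) * B)
  tot <- 2 * a + b + cc_
  m <- pmin(b, cc_)
  beta_sor <- ifelse(tot > 0, (b + cc_) / tot, NA_real_)
  beta_sim <- ifelse(tot > 0, ifelse(a + m > 0, m / (a + m), 0), NA_real_)
  beta_sne <- beta_sor - beta_sim
  list(beta_sor = matrix(beta_sor, dims[1], dims[2]),
       beta_sim = matrix(beta_sim, dims[1], dims[2]),
       beta_sne = matrix(beta_sne, dims[1], dims[2]))
}

#' Habitat range-size change between two regimes
#'
#' Four-way per-pixel classification between a baseline map A and a
#' comparison map B: loss (present to absent), gain (absent to present),
#' stable-present, stable-absent. Percentages are relative to
#' baseline-present cells; the direction is the sign of `gain - loss`
#' (accrual / reduction / unchanged).
#'
#' @param binary_A,binary_B logical matrices (baseline, comparison).
#' @param grid optional `arc_grid`; restricts counting to ocean cells and
#'   adds a per-region table.
#' @param species_id optional label carried through.
#' @return an `arc_range_change` list: counts, percentages, `direction`,
#'   `category` matrix (`"loss"`, `"gain"`, `"stable_present"`,
#'   `"stable_absent"`, NA off-domain), `regional` table when `grid` given.
#' @export
range_size_change <- function(binary_A, binary_B, grid = NULL,
                              species_id = NA_character_) {
  stopifnot(identical(dim(binary_A), dim(binary_B)))
  dom <- if (is.null(grid)) matrix(TRUE, nrow(binary_A), ncol(binary_A))
         else ocean_mask(grid)
  cat <- matrix(NA_character_, nrow(binary_A), ncol(binary_A))
  cat[dom & binary_A & !binary_B] <- "loss"
  cat[dom & !binary_A & binary_B] <- "gain"
  cat[dom & binary_A & binary_B] <- "stable_present"
  cat[dom & !binary_A & !binary_B] <- "stable_absent"
  n <- c(loss = sum(cat == "loss", na.rm = TRUE),
         gain = sum(cat == "gain", na.rm = TRUE),
         stable_present = sum(cat == "stable_present", na.rm = TRUE),
         stable_absent = sum(cat == "stable_absent", na.rm = TRUE))
  baseline <- n[["loss"]] + n[["stable_present"]]
  pct <- if (baseline > 0) 100 * n / baseline else n * NA_real_
  direction <- if (n[["gain"]] > n[["loss"]]) "accrual"
               else if (n[["gain"]] < n[["loss"]]) "reduction" else "unchanged"
  out <- list(species_id = species_id, n = n, pct_of_baseline = pct,
              direction = direction, category = cat)
  if (!is.null(grid)) {
    regions <- sort(setdiff(unique(as.vector(grid$region_id)), 0L))
    out$regional <- do.call(rbind, lapply(regions, function(r) {
      inr <- grid$region_id == r & dom
      g <- sum(cat == "gain" & inr, na.rm = TRUE)
      l <- sum(cat == "loss" & inr, na.rm = TRUE)
      data.frame(species_id = species_id, region = r, n_gain = g, n_loss = l,
                 direction = if (g > l) "accrual"
                             else if (g < l) "reduction" else "unchanged")
    }))
  }
  structure(out, class = "arc_range_change")
}

#' Average annual binaries over a year subset and re-binarize
#'
#' The regime map: per-pixel mean of the subset's annual binary maps,
#' thresholded at 0.5 (boundary counts as present).
#'
#' @param annual_binaries named list of logical matrices keyed by year (as
#'   character) or an unnamed list aligned with `years`.
#' @param years_subset years to average over (non-empty).
#' @param years optional year vector aligning an unnamed list.
#' @return logical matrix.
#' @export
regime_average_binary <- function(annual_binaries, years_subset, years = NULL) {
  if (!length(years_subset)) stop("years_subset must be non-empty")
  if (is.null(names(annual_binaries))) {
    stopifnot(!is.null(years), length(annual_binaries) == length(years))
    names(annual_binaries) <- as.character(years)
  }
  keys <- as.character(years_subset)
  missing <- setdiff(keys, names(annual_binaries))
  if (length(missing)) stop("years missing from stack: ",
                            paste(missing, collapse = ", "))
  maps <- annual_binaries[keys]
  Reduce(`+`, lapply(maps, function(m) m * 1)) / length(maps) >= 0.5
}
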