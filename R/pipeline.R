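# Configured end-to-end pipeline: simulate -> prep -> fit -> predict ->
# biodiversity -> co-occurrence -> climate -> report, with a manifest of
# every artifact written.

#' Default pipeline configuration
#'
#' `scale = "desk"` is the default synthetic scenario: a 1-degree pan-Arctic
#' grid (40 x 360 cells, 50-90 N), 20 years (2000-2019), 8 marine regions
#' and 12 species (4 apex, 8 meso), with 500 pseudo-absences per year
#' standing in for the study-scale 10000. `scale = "tiny"` is a minutes-fast
#' smoke scenario for tests and demos.
#'
#' @param scale `"desk"` or `"tiny"`.
#' @param seed master seed; every stage derives a named sub-seed.
#' @return nested configuration list (see fields in source).
#' @export
default_config <- function(scale = c("desk", "tiny"), seed = 1) {
  scale <- match.arg(scale)
  cfg <- list(
    seed = seed,
    grid = list(extent = c(-180, 180, 50, 90), cell_size_deg = 1,
                n_regions = 8),
    years = 2000:2019,
    species = list(n_apex = 4, n_meso = 8),
    sampling = list(n_per_year = 120),
    thinning = list(thin_km = 100, n_reps = 10),
    pseudoabsence = list(n_per_year = 500, buffer_km = 100,
                         profile_rule = "any_outside"),
    # n_splits = 2 at desk scale keeps the 12-species default run inside a
    # single-CPU budget; fit_species_ensemble() itself defaults to 3
    sdm = list(algorithms = names(sdm_algorithms()), tss_gate = 0.7,
               n_splits = 2, candidate_variables = ENV_ALL_VARS,
               variable_selection = TRUE, importance_n_perm = 3),
    biodiversity = list(accrual_per_decade = 1),
    cooccurrence = list(alpha = 0.05, min_expected = 1),
    climate = list(p_max = 0.05, min_indicators = 2,
                   bounds = default_hotspot_bounds(),
                   climatology = "baseline"),
    output = list(write_rasters = TRUE)
  )
  if (scale == "tiny") {
    cfg$grid <- list(extent = c(-180, -60, 50, 75), cell_size_deg = 2,
                     n_regions = 4)
    cfg$years <- 2000:2009
    cfg$species <- list(n_apex = 2, n_meso = 4)
    cfg$sampling$n_per_year <- 60
    cfg$pseudoabsence$n_per_year <- 150
    cfg$sdm$algorithms <- c("glm_ridge", "boosted_trees")
    cfg$sdm$n_splits <- 2
    cfg$thinning$thin_km <- 50
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and out-of-range numeric parameters before any
#' compute happens.
#'
#' @param config configuration list.
#' @return the config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(ref[[sec]]) && !is.null(names(ref[[sec]]))) {
      bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
      if (length(bad)) stop("unknown config key(s) in ", sec, ": ",
                            paste(bad, collapse = ", "))
    }
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid config: ", msg)
  chk(length(config$years) >= 4, "need >= 4 years")
  chk(config$grid$cell_size_deg > 0, "cell_size_deg must be positive")
  chk(config$grid$n_regions >= 1, "n_regions must be >= 1")
  chk(config$thinning$thin_km > 0, "thin_km must be positive")
  chk(config$pseudoabsence$n_per_year >= 1, "n_per_year must be >= 1")
  chk(config$pseudoabsence$buffer_km >= 0, "buffer_km must be >= 0")
  chk(config$sdm$tss_gate >= -1 && config$sdm$tss_gate <= 1,
      "tss_gate must be in [-1, 1]")
  chk(config$cooccurrence$alpha > 0 && config$cooccurrence$alpha < 1,
      "alpha must be in (0, 1)")
  chk(config$biodiversity$accrual_per_decade >= 0,
      "accrual_per_decade must be >= 0")
  invisible(config)
}

write_table <- function(df, path, manifest) {
  utils::write.csv(df, path, row.names = FALSE)
  manifest$files <- c(manifest$files, path)
  manifest
}

raster_to_long <- function(mat, grid, name, extra = list()) {
  cc <- cell_coords(grid)
  df <- data.frame(lat = cc$lat, lon = cc$lon, value = as.vector(mat))
  for (k in names(extra)) df[[k]] <- extra[[k]]
  df$layer <- name
  df
}

#' Fit and predict the ensemble for one species (two-round protocol)
#'
#' Round 1: random buffered pseudo-absences, all candidate covariates,
#' permutation importance averaged across algorithms, mean-importance
#' variable selection. Round 2: environmental profile from the pooled
#' presences on the selected variables, profiled pseudo-absences, final
#' ensemble fit. Predictions are committee-mean annual binary maps
#' constrained to the species' allowed regions.
#'
#' @param species an `arc_species`.
#' @param env an `arc_env`.
#' @param presences cleaned, thinned occurrences of this species.
#' @param config pipeline configuration.
#' @param predict_years years to map (default all stack years).
#' @return list: `fit` (`arc_ensemble_fit`), `variables`, `binaries`
#'   (named list year -> logical matrix), `profile`.
#' @export
fit_species_pipeline <- function(species, env, presences, config,
                                 predict_years = env$years) {
  grid <- env$grid
  seed <- config$seed
  pa_cfg <- config$pseudoabsence
  cand <- config$sdm$candidate_variables
  years_p <- sort(unique(presences$year))
  draw_pa <- function(mode, profile = NULL, vars) {
    do.call(rbind, lapply(years_p, function(y)
      sample_pseudoabsences(grid, env, presences, y,
                            n_target = pa_cfg$n_per_year,
                            buffer_km = pa_cfg$buffer_km,
                            mode = mode, profile = profile, variables = vars,
                            profile_rule = pa_cfg$profile_rule,
                            seed = sub_seed(seed, paste0(mode, "_",
                                                         species$species_id)))))
  }
  vars <- cand
  if (isTRUE(config$sdm$variable_selection)) {
    pa1 <- draw_pa("random", vars = cand)
    tr1 <- build_training_set(env, presences, pa1, cand)
    m1 <- fit_single_models(tr1, cand, config$sdm$algorithms,
                            seed = sub_seed(seed, paste0("r1_", species$species_id)))
    imp <- do.call(rbind, lapply(m1, permutation_importance, data = tr1,
                                 n_perm = config$sdm$importance_n_perm,
                                 seed = sub_seed(seed, species$species_id)))
    vars <- select_variables(imp)
    if (length(vars) < 2)  # model contracts need >= 2 covariates
      vars <- unique(c(vars, cand))[1:2]
  }
  pres_cov <- cbind(presences,
                    extract_covariates(env, presences, vars))
  profile <- build_env_profile(pres_cov, vars)
  pa2 <- draw_pa("profiled", profile = profile, vars = vars)
  train <- build_training_set(env, presences, pa2, vars)
  fit <- fit_species_ensemble(train, vars,
                              algorithms = config$sdm$algorithms,
                              tss_gate = config$sdm$tss_gate,
                              n_splits = config$sdm$n_splits,
                              seed = sub_seed(seed, paste0("ens_",
                                                           species$species_id)))
  binaries <- lapply(predict_years, function(y)
    predict_ensemble(fit, env, y, species$allowed_regions)$binary_map)
  names(binaries) <- as.character(predict_years)
  list(fit = fit, variables = vars, binaries = binaries, profile = profile)
}

#' Run the full pipeline
#'
#' Executes simulate -> prep -> fit -> predict -> biodiversity ->
#' co-occurrence -> climate and writes all declared CSV/JSON artifacts plus
#' a manifest (config hash, seed, per-stage counts, file checksums) into
#' `out_dir`. Reruns with the same config are bit-identical. Species whose
#' ensemble has no member passing the TSS gate are excluded from the
#' community analyses and logged in the manifest.
#'
#' @param config configuration from [default_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  manifest <- list(config = config, files = character(), stages = list())
  seed <- config$seed

  message("[simulate] grid + environment")
  grid <- make_grid(config$grid$extent, config$grid$cell_size_deg,
                    config$grid$n_regions, seed = seed)
  env <- simulate_environment(grid, config$years, seed = seed)
  species <- default_species_set(env, config$species$n_apex,
                                 config$species$n_meso, seed = seed)
  manifest$stages$simulate <- list(n_cells = sum(!grid$land_mask),
                                   n_years = length(env$years),
                                   n_species = length(species))

  message("[prep] occurrences: sample, clean, thin")
  occ_raw <- do.call(rbind, lapply(species, function(sp)
    do.call(rbind, lapply(env$years, function(y)
      sample_occurrences(sp, env, y, config$sampling$n_per_year,
                         seed = sub_seed(seed, "sampling"))$occurrences))))
  occ <- clean_occurrences(occ_raw, grid)
  occ <- thin_occurrences(occ, config$thinning$thin_km,
                          config$thinning$n_reps,
                          seed = sub_seed(seed, "thin_stage"))
  manifest <- write_table(occ, p("occurrences.csv"), manifest)
  manifest$stages$prep <- list(raw = nrow(occ_raw), thinned = nrow(occ))

  message("[fit/predict] per-species ensembles")
  guilds <- stats::setNames(vapply(species, `[[`, character(1), "guild"),
                            vapply(species, `[[`, character(1), "species_id"))
  binaries <- list(); eval_rows <- list(); skipped <- character()
  for (sp in species) {
    pres <- occ[occ$species_id == sp$species_id, , drop = FALSE]
    res <- tryCatch(
      fit_species_pipeline(sp, env, pres, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("species ", sp$species_id, " excluded: ", conditionMessage(res))
      skipped <- c(skipped, sp$species_id)
      next
    }
    binaries[[sp$species_id]] <- res$binaries
    ev <- res$fit$evaluation
    ev$species_id <- sp$species_id
    eval_rows[[sp$species_id]] <- ev
  }
  if (!length(binaries)) stop("fit stage failed: no species retained")
  manifest <- write_table(do.call(rbind, eval_rows), p("evaluations.csv"),
                          manifest)
  manifest$stages$fit <- list(n_species = length(binaries), skipped = skipped)
  kept <- names(binaries)
  guilds <- guilds[kept]

  message("[biodiversity] richness, trends, accrual")
  years <- env$years
  stack_year <- function(ids, t) lapply(stats::setNames(ids, ids),
                                        function(s) binaries[[s]][[t]])
  sr_all <- list(); sr_apex <- list(); sr_meso <- list()
  for (t in as.character(years)) {
    sr_all[[t]] <- richness_stack(stack_year(kept, t))
    a <- kept[guilds == "apex"]; m <- kept[guilds == "meso"]
    sr_apex[[t]] <- if (length(a)) richness_stack(stack_year(a, t)) else
      sr_all[[t]] * 0L
    sr_meso[[t]] <- if (length(m)) richness_stack(stack_year(m, t)) else
      sr_all[[t]] * 0L
  }
  regions <- sort(setdiff(unique(as.vector(grid$region_id)), 0L))
  sr_series <- do.call(rbind, lapply(regions, function(r) {
    inr <- grid$region_id == r & !grid$land_mask
    do.call(rbind, lapply(seq_along(years), function(t)
      data.frame(region = r, year = years[t],
                 SR_all = mean(sr_all[[t]][inr]),
                 SR_apex = mean(sr_apex[[t]][inr]),
                 SR_meso = mean(sr_meso[[t]][inr]))))
  }))
  manifest <- write_table(sr_series, p("richness_series.csv"), manifest)
  trend <- richness_trend(sr_all, years, grid)
  manifest <- write_table(trend$regional, p("richness_trend_regional.csv"),
                          manifest)
  sst_anom <- summer_anomaly(env, "SSST", config$climate$climatology)
  acc <- accrual_mask(trend, config$biodiversity$accrual_per_decade, grid,
                      sr_all, years, sst_anom)
  manifest <- write_table(acc$region_freq, p("accrual_region_freq.csv"),
                          manifest)
  hov <- acc$series
  ssic_anom <- summer_anomaly(env, "SSIC", config$climate$climatology)
  regimes <- classify_ice_regimes(ssic_anom)
  hov <- merge(hov, regimes$per_region, by = c("region", "year"))
  hov <- merge(hov, sst_anom[, c("region", "year", "anomaly")],
               by = c("region", "year"))
  names(hov)[names(hov) == "regime"] <- "ice_regime_flag"
  names(hov)[names(hov) == "anomaly"] <- "sst_anomaly"
  manifest <- write_table(hov[order(hov$region, hov$year), ],
                          p("accrual_hovmoller.csv"), manifest)

  message("[regimes] range-size change and beta diversity")
  low <- regimes$pooled_low; high <- regimes$pooled_high
  if (length(low) && length(high)) {
    reg_maps <- lapply(kept, function(s) list(
      high = regime_average_binary(binaries[[s]], high),
      low = regime_average_binary(binaries[[s]], low)))
    names(reg_maps) <- kept
    rc <- do.call(rbind, lapply(kept, function(s) {
      r <- range_size_change(reg_maps[[s]]$high, reg_maps[[s]]$low, grid, s)
      data.frame(species_id = s, n_loss = r$n[["loss"]],
                 n_gain = r$n[["gain"]],
                 n_stable_present = r$n[["stable_present"]],
                 n_stable_absent = r$n[["stable_absent"]],
                 direction = r$direction)
    }))
    manifest <- write_table(rc, p("range_size_change.csv"), manifest)
    beta <- beta_decompose(
      lapply(stats::setNames(kept, kept), function(s) reg_maps[[s]]$high),
      lapply(stats::setNames(kept, kept), function(s) reg_maps[[s]]$low))
    beta_reg <- do.call(rbind, lapply(regions, function(r) {
      inr <- grid$region_id == r & !grid$land_mask
      data.frame(region = r,
                 beta_sor = mean(beta$beta_sor[inr], na.rm = TRUE),
                 beta_sim = mean(beta$beta_sim[inr], na.rm = TRUE),
                 beta_sne = mean(beta$beta_sne[inr], na.rm = TRUE))
    }))
    manifest <- write_table(beta_reg, p("beta_regional.csv"), manifest)
  } else {
    beta <- NULL
    warning("empty pooled ice regime; regime contrasts skipped")
  }
  manifest <- write_table(regimes$per_region, p("ice_regimes.csv"), manifest)

  message("[cooccurrence] pairwise classification per region-year")
  pair_rows <- list(); count_rows <- list()
  for (r in regions) {
    for (t in seq_along(years)) {
      mat <- build_matrix(stack_year(kept, as.character(years[t])), grid, r,
                          period = years[t])
      rc <- region_cooccurrence(mat, config$cooccurrence$alpha,
                                config$cooccurrence$min_expected)
      pair_rows[[length(pair_rows) + 1L]] <- rc$pairs
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        region = r, year = years[t],
        positive = rc$counts[["positive"]],
        negative = rc$counts[["negative"]],
        random = rc$counts[["random"]],
        unanalyzable = rc$n_unanalyzable)
    }
  }
  pairs_df <- do.call(rbind, pair_rows)
  counts_df <- do.call(rbind, count_rows)
  manifest <- write_table(pairs_df, p("cooccurrence_pairs.csv"), manifest)
  manifest <- write_table(counts_df, p("cooccurrence_counts.csv"), manifest)
  cotrend <- do.call(rbind, lapply(regions, function(r) {
    s <- counts_df[counts_df$region == r, ]
    sr <- sr_series[sr_series$region == r, ]
    tr <- cooccurrence_trend(s, sr$SR_all[match(s$year, sr$year)])
    tr$region <- r
    tr
  }))
  manifest <- write_table(cotrend, p("cooccurrence_trends.csv"), manifest)

  message("[climate] Mann-Kendall trends and hotspots")
  oc <- ocean_mask(grid)
  mk_maps <- lapply(stats::setNames(names(config$climate$bounds),
                                    names(config$climate$bounds)),
                    function(v) mk_trend_map(env$layers[[v]], years, oc))
  hs <- hotspot_map(mk_maps, config$climate$bounds, config$climate$p_max,
                    config$climate$min_indicators, acc$mask, grid)
  anoms <- rbind(sst_anom[, c("region", "year", "variable", "anomaly")],
                 ssic_anom[, c("region", "year", "variable", "anomaly")])
  manifest <- write_table(anoms, p("anomalies.csv"), manifest)
  manifest <- write_table(hs$overlap, p("hotspot_overlap.csv"), manifest)

  if (isTRUE(config$output$write_rasters)) {
    rast <- rbind(
      raster_to_long(trend$slope, grid, "richness_slope"),
      raster_to_long(acc$mask * 1L, grid, "accrual_mask"),
      raster_to_long(hs$hotspot * 1L, grid, "hotspot_mask"),
      if (!is.null(beta)) raster_to_long(beta$beta_sor, grid, "beta_sor"))
    manifest <- write_table(rast, p("rasters_long.csv"), manifest)
  }

  manifest$seed <- seed
  manifest$config_hash <- digest_config(config)
  sums <- tools::md5sum(manifest$files)
  names(sums) <- basename(names(sums))   # location-independent manifest
  manifest$checksums <- as.list(sums)
  manifest$files <- basename(manifest$files)
  json <- p("manifest.json")
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  message("pipeline complete: ", length(manifest$files), " artifacts in ",
          out_dir)
  invisible(manifest)
}

# Stable hash of the config (content-addressed manifest entry).
digest_config <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
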