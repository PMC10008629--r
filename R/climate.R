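# Summer anomalies, sea-ice regime classification, pixel-wise Mann-Kendall
# trends with Sen slopes, and >=2-of-4 climate/productivity hotspots.

#' Regional summer anomalies of an environmental variable
#'
#' Annual regional-mean values minus a regional climatology mean. The
#' synthetic climatology is the scenario's truth baseline field (standing in
#' for a long pre-record average); alternatively the mean of the first `k`
#' years can be used. Temperature anomalies additionally carry a
#' moderate/high-warming flag at >= 0.5 degrees C.
#'
#' @param env an `arc_env`.
#' @param variable variable name in the stack.
#' @param climatology `"baseline"` (truth baseline field) or `"first_k"`.
#' @param k years in the `"first_k"` climatology (default 10).
#' @return data.frame `region, year, variable, anomaly` (+ `warming_flag`
#'   for SSST).
#' @export
summer_anomaly <- function(env, variable, climatology = c("baseline", "first_k"),
                           k = 10) {
  climatology <- match.arg(climatology)
  if (!variable %in% names(env$layers)) stop("unknown variable: ", variable)
  grid <- env$grid
  regions <- sort(setdiff(unique(as.vector(grid$region_id)), 0L))
  arr <- env$layers[[variable]]
  rows <- list()
  for (r in regions) {
    inr <- grid$region_id == r & !grid$land_mask
    series <- vapply(seq_along(env$years),
                     function(t) mean(arr[, , t][inr]), numeric(1))
    clim <- if (climatology == "baseline") {
      base <- env$truth$baseline[[variable]]
      if (is.null(base)) stop("no truth baseline for ", variable,
                              "; use climatology = 'first_k'")
      mean(base[inr])
    } else mean(series[seq_len(min(k, length(series)))])
    df <- data.frame(region = r, year = env$years, variable = variable,
                     anomaly = series - clim)
    if (variable == "SSST") df$warming_flag <- df$anomaly >= 0.5
    rows[[length(rows) + 1L]] <- df
  }
  do.call(rbind, rows)
}

#' Classify years into low and high sea-ice regimes per region
#'
#' A year is low-ice in a region when its summer sea-ice-concentration
#' anomaly is negative, high-ice otherwise. Pooled sets are the years
#' classified the same way in every region (the basis for pan-regime
#' contrasts); empty pooled sets trigger a warning rather than an error.
#'
#' @param ssic_anomalies data.frame `region, year, anomaly`.
#' @return an `arc_ice_regimes` list: `per_region` (data.frame
#'   `region, year, regime`), `pooled_low`, `pooled_high`.
#' @export
classify_ice_regimes <- function(ssic_anomalies) {
  if (length(unique(ssic_anomalies$year)) < 2) stop("need at least 2 years")
  per <- data.frame(region = ssic_anomalies$region,
                    year = ssic_anomalies$year,
                    regime = ifelse(ssic_anomalies$anomaly < 0, "low", "high"))
  regions <- unique(per$region)
  years <- sort(unique(per$year))
  all_low <- years; all_high <- years
  for (r in regions) {
    pr <- per[per$region == r, ]
    all_low <- intersect(all_low, pr$year[pr$regime == "low"])
    all_high <- intersect(all_high, pr$year[pr$regime == "high"])
  }
  if (!length(all_low) || !length(all_high))
    warning("pooled regime set empty: regions disagree on ",
            if (!length(all_low)) "low" else "high", "-ice years")
  structure(list(per_region = per,
                 pooled_low = sort(all_low), pooled_high = sort(all_high)),
            class = "arc_ice_regimes")
}

#' Mann-Kendall trend test with Sen slope
#'
#' `S` is the sum of pairwise concordance signs; `var_S` applies the tie
#' correction `[n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18`; the normal
#' z-score uses the +-1 continuity correction and is 0 when `S = 0`; `p`
#' is two-sided. The Sen slope is the median of all pairwise slopes.
#'
#' @param x numeric series (>= 4 non-missing values).
#' @param years optional time coordinates (default `1:n`).
#' @return list `S, var_S, z, p, sen_slope, n`.
#' @export
mann_kendall <- function(x, years = NULL) {
  ok <- is.finite(x)
  x <- x[ok]
  n <- length(x)
  if (n < 4) stop("Mann-Kendall needs at least 4 non-missing values")
  t_ <- if (is.null(years)) seq_len(n) else years[ok]
  pr <- utils::combn(n, 2)
  dx <- x[pr[2, ]] - x[pr[1, ]]
  dt <- t_[pr[2, ]] - t_[pr[1, ]]
  S <- sum(sign(dx))
  ties <- table(x)
  tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
  var_S <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- if (S > 0) (S - 1) / sqrt(var_S)
       else if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(S = S, var_S = var_S, z = z, p = p,
       sen_slope = stats::median(dx / dt), n = n)
}

#' Pixel-wise Mann-Kendall trend map
#'
#' Vectorised over pixels: S and Sen slope from the precomputed pair
#' differences, tie-corrected variance per pixel.
#'
#' @param values_by_year list of matrices (one per year, in order) or a
#'   3-d array `rows x cols x years`.
#' @param years calendar years.
#' @param mask optional logical matrix restricting computation.
#' @return an `arc_mk_map`: matrices `S, var_S, z, p, sen_slope`.
#' @export
mk_trend_map <- function(values_by_year, years, mask = NULL) {
  if (is.list(values_by_year)) {
    dims <- dim(values_by_year[[1]])
    V <- vapply(values_by_year, as.vector, numeric(prod(dims)))
  } else {
    dims <- dim(values_by_year)[1:2]
    V <- matrix(values_by_year, prod(dims), dim(values_by_year)[3])
  }
  n <- length(years)
  stopifnot(ncol(V) == n, n >= 4)
  sel <- if (is.null(mask)) seq_len(nrow(V)) else which(as.vector(mask))
  pr <- utils::combn(n, 2)
  dt <- years[pr[2, ]] - years[pr[1, ]]
  D <- V[sel, pr[2, ], drop = FALSE] - V[sel, pr[1, ], drop = FALSE]
  S <- rowSums(sign(D))
  sen <- apply(sweep(D, 2, dt, "/"), 1, stats::median)
  tie_term <- apply(V[sel, , drop = FALSE], 1, function(r) {
    tt <- table(r)
    sum(tt * (tt - 1) * (2 * tt + 5))
  })
  var_S <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- ifelse(S > 0, (S - 1) / sqrt(var_S),
              ifelse(S < 0, (S + 1) / sqrt(var_S), 0))
  z[var_S == 0] <- 0
  p <- 2 * stats::pnorm(-abs(z))
  blank <- matrix(NA_real_, dims[1], dims[2])
  out <- list()
  for (nm in c("S", "var_S", "z", "p", "sen_slope")) out[[nm]] <- blank
  out$S[sel] <- S; out$var_S[sel] <- var_S; out$z[sel] <- z
  out$p[sel] <- p; out$sen_slope[sel] <- sen
  structure(c(out, list(n_years = n)), class = "arc_mk_map")
}

#' Default decadal-magnitude bounds for "large" changes
#'
#' Signed decadal Sen-slope windows for the four screened variables:
#' warming (SSST up), ice loss (SSIC down), and productivity increases
#' (SCHL, SZOOC up). Defaults follow decadal-change magnitudes reported for
#' recent pan-Arctic summers; override per deployment via the pipeline
#' config.
#'
#' @return named list `variable -> c(lower, upper)` (units per decade).
#' @export
default_hotspot_bounds <- function() {
  list(SSST = c(0.21, 0.76), SSIC = c(-76, -2),
       SCHL = c(0.26, 0.73), SZOOC = c(0.21, 0.75))
}

#' Climate/productivity hotspots and their overlap with accrual areas
#'
#' A pixel shows a "large change" in a variable when its Mann-Kendall trend
#' is significant (p < `p_max`) and its decadal Sen slope falls inside that
#' variable's signed magnitude window. A hotspot is a pixel with large
#' changes in at least `min_indicators` of the four variables. With an
#' accrual mask and grid, per-region percentages of accrual cells
#' overlapping the hotspot mask and each single-variable mask are reported.
#'
#' @param trend_maps named list of `arc_mk_map` (names SSST, SSIC, SCHL,
#'   SZOOC or a subset; all on one grid).
#' @param bounds per-variable decadal windows, see
#'   [default_hotspot_bounds()].
#' @param p_max Mann-Kendall significance cut (default 0.05).
#' @param min_indicators hotspot count rule (default 2).
#' @param accrual optional logical accrual mask.
#' @param grid optional `arc_grid` for regional overlap statistics.
#' @return an `arc_hotspot_map`: `indicators` (named list of logical
#'   matrices), `n_large`, `hotspot`, `overlap` (data.frame
#'   `region, mask, percent_accrual_overlap`).
#' @export
hotspot_map <- function(trend_maps, bounds = default_hotspot_bounds(),
                        p_max = 0.05, min_indicators = 2,
                        accrual = NULL, grid = NULL) {
  vars <- names(bounds)
  missing <- setdiff(vars, names(trend_maps))
  if (length(missing)) stop("missing trend map(s): ",
                            paste(missing, collapse = ", "))
  indicators <- lapply(vars, function(v) {
    tm <- trend_maps[[v]]
    dec <- tm$sen_slope * 10
    ind <- tm$p < p_max & dec >= bounds[[v]][1] & dec <= bounds[[v]][2]
    ind[is.na(ind)] <- FALSE
    ind
  })
  names(indicators) <- vars
  n_large <- Reduce(`+`, lapply(indicators, function(m) m * 1L))
  hotspot <- n_large >= min_indicators
  out <- list(indicators = indicators, n_large = n_large, hotspot = hotspot)
  if (!is.null(accrual) && !is.null(grid)) {
    regions <- sort(setdiff(unique(as.vector(grid$region_id)), 0L))
    masks <- c(list(hotspot = hotspot), indicators)
    rows <- list()
    for (r in regions) {
      inr <- grid$region_id == r & !grid$land_mask
      n_acc <- sum(accrual & inr)
      for (m in names(masks)) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, mask = m,
          percent_accrual_overlap = if (n_acc > 0)
            100 * sum(accrual & inr & masks[[m]]) / n_acc else NA_real_)
      }
    }
    out$overlap <- do.call(rbind, rows)
  }
  structure(out, class = "arc_hotspot_map")
}
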