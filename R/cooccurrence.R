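# Probabilistic pairwise species co-occurrence: exact hypergeometric null
# implemented from first principles in log-space, with
# positive/negative/random classification and temporal class-count trends.

#' Exact probabilistic co-occurrence test for one species pair
#'
#' Under the null that two species with fixed numbers of occupied sites
#' (`N1`, `N2`) are placed independently among `N` sites, the number of
#' co-occupied sites `Q` is hypergeometric:
#' `P(Q = j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2)` over the feasible
#' range `max(0, N1 + N2 - N) <= j <= min(N1, N2)`. `p_gt` is the
#' probability of co-occurring at least as often as observed, `p_lt` at
#' most as often; the pair is classified positive when `p_gt < alpha`,
#' negative when `p_lt < alpha`, random otherwise. Binomials are evaluated
#' as log-gammas so large `N` is safe.
#'
#' @param N number of sites.
#' @param N1,N2 occupied-site counts of the two species.
#' @param Q_obs observed number of co-occupied sites.
#' @param alpha significance level (default 0.05).
#' @param sp1,sp2 optional labels.
#' @return an `arc_pair` list: `sp1, sp2, N, N1, N2, Q_obs, expected,
#'   p_lt, p_gt, class`.
#' @export
pair_test <- function(N, N1, N2, Q_obs, alpha = 0.05,
                      sp1 = NA_character_, sp2 = NA_character_) {
  if (N < 1 || N1 < 0 || N2 < 0 || N1 > N || N2 > N)
    stop("invalid site counts: need 0 <= N1, N2 <= N")
  jmin <- max(0, N1 + N2 - N)
  jmax <- min(N1, N2)
  if (Q_obs < jmin || Q_obs > jmax)
    stop(sprintf("Q_obs = %d violates combinatorial bounds [%d, %d]",
                 Q_obs, jmin, jmax))
  j <- jmin:jmax
  logp <- lchoose(N1, j) + lchoose(N - N1, N2 - j) - lchoose(N, N2)
  pmf <- exp(logp)
  pmf <- pmin(pmax(pmf, 0), 1)
  p_lt <- min(1, sum(pmf[j <= Q_obs]))
  p_gt <- min(1, sum(pmf[j >= Q_obs]))
  cls <- if (p_gt < alpha) "positive" else if (p_lt < alpha) "negative"
         else "random"
  structure(list(sp1 = sp1, sp2 = sp2, N = N, N1 = N1, N2 = N2,
                 Q_obs = Q_obs, expected = N1 * N2 / N,
                 p_lt = p_lt, p_gt = p_gt, class = cls),
            class = "arc_pair")
}

#' Site-by-species incidence matrix for one region
#'
#' One row per in-region ocean cell, one column per species. Species never
#' present in the region are retained as all-zero columns (and flagged) but
#' excluded from pair testing downstream.
#'
#' @param binaries named list of logical matrices (one per species).
#' @param grid an `arc_grid`.
#' @param region region id.
#' @param period label (year or regime tag) carried through.
#' @return list: `M` (0/1 sites x species matrix), `region`, `period`,
#'   `sites` (cell indices), `empty_species`.
#' @export
build_matrix <- function(binaries, grid, region, period = NA) {
  sel <- grid$region_id == region & !grid$land_mask
  if (!any(sel)) stop("region ", region, " has no ocean cells")
  idx <- which(as.vector(sel))
  M <- vapply(binaries, function(m) as.integer(as.vector(m)[idx]),
              integer(length(idx)))
  if (!is.matrix(M)) M <- matrix(M, nrow = length(idx),
                                 dimnames = list(NULL, names(binaries)))
  list(M = M, region = region, period = period, sites = idx,
       empty_species = colnames(M)[colSums(M) == 0])
}

#' Test all species pairs within a region
#'
#' Enumerates unordered pairs of species with at least one occupied site;
#' pairs whose expected co-occurrence `N1 N2 / N` falls below `min_expected`
#' are flagged unanalyzable and excluded from the class counts (they are
#' logged, not dropped silently).
#'
#' @param matrix_obj output of [build_matrix()].
#' @param alpha significance level (default 0.05).
#' @param min_expected analyzability filter (default 1).
#' @return list: `pairs` (data.frame
#'   `region, period, sp1, sp2, N, N1, N2, Q_obs, expected, p_lt, p_gt,
#'   class, analyzable`), `counts` (positive/negative/random),
#'   `n_unanalyzable`, `excluded_species`.
#' @export
region_cooccurrence <- function(matrix_obj, alpha = 0.05, min_expected = 1) {
  M <- matrix_obj$M
  occ <- colSums(M)
  sp <- colnames(M)[occ > 0]
  rows <- list()
  if (length(sp) >= 2) {
    Msub <- M[, sp, drop = FALSE]
    Q <- crossprod(Msub)
    N <- nrow(Msub)
    for (i in seq_len(length(sp) - 1)) {
      for (k in (i + 1):length(sp)) {
        pt <- pair_test(N, occ[[sp[i]]], occ[[sp[k]]], Q[i, k],
                        alpha = alpha, sp1 = sp[i], sp2 = sp[k])
        rows[[length(rows) + 1L]] <- data.frame(
          region = matrix_obj$region, period = matrix_obj$period,
          sp1 = pt$sp1, sp2 = pt$sp2, N = pt$N, N1 = pt$N1, N2 = pt$N2,
          Q_obs = pt$Q_obs, expected = pt$expected,
          p_lt = pt$p_lt, p_gt = pt$p_gt, class = pt$class,
          analyzable = pt$expected >= min_expected)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = integer(), period = character(), sp1 = character(),
               sp2 = character(), N = integer(), N1 = integer(),
               N2 = integer(), Q_obs = integer(), expected = numeric(),
               p_lt = numeric(), p_gt = numeric(), class = character(),
               analyzable = logical())
  ok <- pairs[pairs$analyzable, , drop = FALSE]
  counts <- c(positive = sum(ok$class == "positive"),
              negative = sum(ok$class == "negative"),
              random = sum(ok$class == "random"))
  list(pairs = pairs, counts = counts,
       n_unanalyzable = sum(!pairs$analyzable),
       excluded_species = matrix_obj$empty_species)
}

#' Temporal trend of co-occurrence class counts and their richness coupling
#'
#' Per class: OLS slope of annual counts on year, two-sided p, adjusted
#' R-squared, and the Pearson correlation (with p) between the class-count
#' series and the regional species-richness series. Zero-variance series
#' give slope 0 and missing correlation.
#'
#' @param series data.frame with `year` and columns `positive, negative,
#'   random` (one region).
#' @param richness numeric regional mean richness aligned with
#'   `series$year`.
#' @return data.frame `class, slope, p, adj_R2, r, r_p`.
#' @export
cooccurrence_trend <- function(series, richness = NULL) {
  if (nrow(series) < 3) stop("need at least 3 periods")
  do.call(rbind, lapply(c("positive", "negative", "random"), function(cl) {
    y <- series[[cl]]
    tr <- ols_trend(series$year, y)
    co <- if (is.null(richness)) list(r = NA_real_, p = NA_real_)
          else safe_cor(y, richness)
    data.frame(class = cl, slope = tr$slope, p = tr$p, adj_R2 = tr$adj_r2,
               r = co$r, r_p = co$p)
  }))
}
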