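# Small in-code fixtures shared across test files.

tiny_grid <- function(n_regions = 2, seed = 42) {
  make_grid(extent = c(-20, 20, 50, 62), cell_size_deg = 2,
            n_regions = n_regions, seed = seed)
}

# Noise-free scenario builder: every dynamic variable is deterministic, so
# trend arithmetic is exact.
flat_spec <- function(grid, ssst_base = 8, ssst_trend = 0.3,
                      ssic_base = NULL, ssic_trend = -8, ssst_grad = 0) {
  base <- function(x) matrix(x, grid$n_rows, grid$n_cols)
  lat <- matrix(rep(grid$lat_centers, grid$n_cols), grid$n_rows, grid$n_cols)
  list(
    SSST = list(baseline = base(ssst_base) - ssst_grad * (lat - 56),
                trend_per_decade = ssst_trend,
                noise_sd = 0, interannual_sd = 0, min = -Inf, max = Inf),
    SSIC = list(baseline = if (is.null(ssic_base))
                  pmax(0, pmin(100, (lat - 54) * 10)) else base(ssic_base),
                trend_per_decade = ssic_trend,
                noise_sd = 0, interannual_sd = 0, min = 0, max = 100)
  )
}

tiny_env <- function(grid = tiny_grid(), years = 2000:2009, seed = 7,
                     ssst_grad = 0.6, ...) {
  simulate_environment(grid, years,
                       flat_spec(grid, ssst_grad = ssst_grad, ...),
                       seed = seed)
}

tiny_species <- function(env, opt = 8.3, breadth = 2, prevalence = 0.3,
                         regions = 1:2, guild = "meso") {
  define_virtual_species("sp_test", guild,
                         niche_spec = list(SSST = c(opt, breadth)),
                         prevalence_target = prevalence,
                         allowed_regions = regions)
}

# Separable two-covariate training set: presences cluster at (2, 2),
# absences at (-2, -2).
separable_train <- function(n = 200, gap = 4, sd = 0.5, seed = 1) {
  set.seed(seed)
  half <- n / 2
  data.frame(
    species_id = "toy", year = 2000L,
    longitude = 0, latitude = 55,
    label = rep(c("presence", "pseudo_absence"), each = half),
    v1 = c(rnorm(half, gap / 2, sd), rnorm(half, -gap / 2, sd)),
    v2 = c(rnorm(half, gap / 2, sd), rnorm(half, -gap / 2, sd)))
}

random_binary_stack <- function(n_species, dims, p = 0.4) {
  stats::setNames(lapply(seq_len(n_species), function(i)
    matrix(stats::runif(prod(dims)) < p, dims[1], dims[2])),
    sprintf("s%02d", seq_len(n_species)))
}
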