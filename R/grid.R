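# Regular lon-lat analysis grid with CBMP-style longitude-sector regions.

#' Build the analysis grid
#'
#' A regular latitude-longitude grid with cell-center registration. The
#' non-land domain is partitioned into `n_regions` contiguous longitude
#' sectors (stand-ins for the eight circumpolar monitoring-programme marine
#' areas), and a southern land fringe provides a coastline so that sampling
#' bias and distance-to-coast covariates have something to anchor to.
#'
#' @param extent numeric `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param cell_size_deg cell size in degrees (same in both axes).
#' @param n_regions number of longitude-sector regions (>= 1).
#' @param seed integer seed controlling the (slightly irregular) coastline.
#' @param land_rows how many southern rows form the land fringe (default 2).
#' @return an object of class `arc_grid`: `n_rows`, `n_cols`,
#'   `cell_size_deg`, `lat_centers` (south to north), `lon_centers`,
#'   `region_id` (integer matrix, 0 = outside domain), `land_mask`
#'   (logical matrix). Matrices are `n_rows x n_cols`, row 1 = southernmost.
#' @export
make_grid <- function(extent = c(-180, 180, 50, 90), cell_size_deg = 1,
                      n_regions = 8, seed = 1, land_rows = 2) {
  if (cell_size_deg <= 0) stop("cell_size_deg must be positive")
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(lon_min, lon_max, lat_min, lat_max)")
  if (extent[4] - extent[3] < 10) stop("extent must span at least 10 degrees latitude")
  if (n_regions < 1) stop("n_regions must be >= 1")

  n_cols <- round((extent[2] - extent[1]) / cell_size_deg)
  n_rows <- round((extent[4] - extent[3]) / cell_size_deg)
  lon <- extent[1] + (seq_len(n_cols) - 0.5) * cell_size_deg
  lat <- extent[3] + (seq_len(n_rows) - 0.5) * cell_size_deg

  set.seed(sub_seed(seed, "make_grid"))
  # Land fringe: `land_rows` southern rows, with +-1 row of noise along the
  # coast so land is not a perfectly zonal band.
  depth_of_land <- pmax(0, land_rows + sample(c(-1, 0, 0, 1), n_cols, TRUE))
  land <- matrix(FALSE, n_rows, n_cols)
  for (j in seq_len(n_cols)) if (depth_of_land[j] > 0)
    land[seq_len(min(n_rows, depth_of_land[j])), j] <- TRUE

  sector <- ceiling(seq_len(n_cols) / (n_cols / n_regions))
  sector <- pmin(sector, n_regions)
  region <- matrix(rep(sector, each = n_rows), n_rows, n_cols)
  region[land] <- 0L
  storage.mode(region) <- "integer"

  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size_deg = cell_size_deg,
                 lat_centers = lat, lon_centers = lon,
                 region_id = region, land_mask = land),
            class = "arc_grid")
}

#' @export
print.arc_grid <- function(x, ...) {
  cat(sprintf("<arc_grid> %d x %d cells (%.3g deg), %d regions, %d ocean cells\n",
              x$n_rows, x$n_cols, x$cell_size_deg,
              length(setdiff(unique(as.vector(x$region_id)), 0L)),
              sum(!x$land_mask)))
  invisible(x)
}

# Logical matrix of cells inside the marine domain.
ocean_mask <- function(grid) !grid$land_mask & grid$region_id > 0L

# Cell-center coordinates of every cell, as vectors aligned with
# column-major matrix order (the order `as.vector(<raster matrix>)` uses).
cell_coords <- function(grid) {
  list(lon = rep(grid$lon_centers, each = grid$n_rows),
       lat = rep(grid$lat_centers, times = grid$n_cols))
}

# Map coordinates to (row, col); NA when outside the grid bounds.
coord_to_cell <- function(grid, lon, lat) {
  half <- grid$cell_size_deg / 2
  col <- findInterval(lon, c(grid$lon_centers - half,
                             grid$lon_centers[grid$n_cols] + half))
  row <- findInterval(lat, c(grid$lat_centers - half,
                             grid$lat_centers[grid$n_rows] + half))
  col[col < 1 | col > grid$n_cols] <- NA_integer_
  row[row < 1 | row > grid$n_rows] <- NA_integer_
  bad <- is.na(row) | is.na(col)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = row, col = col,
       index = ifelse(bad, NA_integer_, (col - 1L) * grid$n_rows + row))
}

same_grid <- function(a, b) {
  identical(dim(a$region_id), dim(b$region_id)) &&
    isTRUE(all.equal(a$lat_centers, b$lat_centers)) &&
    isTRUE(all.equal(a$lon_centers, b$lon_centers))
}
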