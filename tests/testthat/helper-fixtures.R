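# Small grids, regions and cubes used across the suite. All fixtures are
# built in code; nothing is read from disk.

tiny_grid <- function(nlat = 4, nlon = 6, res = 15) {
  lat0 <- -res * (nlat - 1) / 2
  lon0 <- -res * (nlon - 1) / 2
  grid_spec(seq(lat0, by = res, length.out = nlat),
            seq(lon0, by = res, length.out = nlon))
}

# Two side-by-side regions covering the whole tiny grid's tropics.
tiny_regions <- function(grid = tiny_grid()) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  half <- floor(nlon / 2)
  cells_a <- as.vector(outer(seq_len(nlat), seq_len(half) - 1L,
                             function(i, j) i + j * nlat))
  cells_b <- setdiff(seq_len(nlat * nlon), cells_a)
  region_set(grid, cells = list(A = cells_a, B = cells_b))
}

# A single-cell-grid cube with a prescribed (member x year) value matrix.
series_cube <- function(values, years = seq_len(ncol(values)) + 1849) {
  g <- grid_spec(0, 0)
  smile_cube(array(values, c(nrow(values), ncol(values), 1)), years, g)
}

# Quick stationary synthetic cube on the tiny grid.
tiny_cube <- function(n_members = 4, years = c(2000, 2049), seed = 1,
                      grid = tiny_grid(), regions = tiny_regions(grid), ...) {
  generate_smile(synthetic_config(n_members, years, grid, regions,
                                  seed = seed, ...))
}

# Random drought mask with matching metadata.
random_mask <- function(grid, n_members, years, p = 0.3, seed = 1) {
  set.seed(seed)
  arr <- array(stats::runif(n_members * length(years) * n_cells(grid)) < p,
               c(n_members, length(years), n_cells(grid)))
  structure(list(mask = arr, years = as.integer(years), grid = grid),
            class = "drought_mask")
}
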