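#' Define a latitude-longitude grid
#'
#' A `grid_spec` holds cell-center coordinates and contiguous cell bounds for a
#' regular (not necessarily uniform) lat-lon grid. Cells are indexed
#' column-major over `(lat, lon)`, matching how an `nlat x nlon` matrix
#' flattens in R, so `matrix(x, nlat, nlon)` maps a cell vector back onto the
#' grid. Longitudes are normalized to `[-180, 180)`.
#'
#' @param lat,lon Numeric vectors of strictly monotone increasing cell-center
#'   coordinates in degrees.
#' @param lat_bounds,lon_bounds Optional `n x 2` matrices of cell edges. When
#'   omitted, edges are placed midway between neighbouring centers and the
#'   outer edges mirror the first/last half-width (clipped to +/-90 for
#'   latitude).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(lat = seq(-60, 60, by = 30), lon = seq(-165, 165, by = 30))
#' n_cells(g)
#' @export
grid_spec <- function(lat, lon, lat_bounds = NULL, lon_bounds = NULL) {
  lon <- normalize_lon(lon)
  if (is.unsorted(lat, strictly = TRUE) || is.unsorted(lon, strictly = TRUE)) {
    stop("grid centers must be strictly increasing (after longitude normalization)",
         call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) stop("latitudes must lie in [-90, 90]", call. = FALSE)
  if (is.null(lat_bounds)) lat_bounds <- centers_to_bounds(lat, clip = c(-90, 90))
  if (is.null(lon_bounds)) lon_bounds <- centers_to_bounds(lon, clip = NULL)
  check_bounds(lat_bounds, lat, "lat")
  check_bounds(lon_bounds, lon, "lon")
  structure(
    list(lat = as.numeric(lat), lon = as.numeric(lon),
         lat_bounds = lat_bounds, lon_bounds = lon_bounds),
    class = "grid_spec"
  )
}

#' Uniform global grid at a given resolution
#'
#' Convenience constructor for the uniform grids ensemble output is commonly
#' regridded to (e.g. 2.5 degrees).
#'
#' @param res Cell size in degrees (same for lat and lon).
#' @return A `grid_spec`.
#' @export
grid_spec_uniform <- function(res = 2.5) {
  lat <- seq(-90 + res / 2, 90 - res / 2, by = res)
  lon <- seq(-180 + res / 2, 180 - res / 2, by = res)
  grid_spec(lat, lon)
}

normalize_lon <- function(lon) ((lon + 180) %% 360) - 180

centers_to_bounds <- function(x, clip = NULL) {
  mid <- (x[-1] + x[-length(x)]) / 2
  lower <- c(x[1] - (mid[1] - x[1]), mid)
  upper <- c(mid, x[length(x)] + (x[length(x)] - mid[length(mid)]))
  if (length(x) == 1) {
    lower <- x - 0.5
    upper <- x + 0.5
  }
  if (!is.null(clip)) {
    lower <- pmax(lower, clip[1])
    upper <- pmin(upper, clip[2])
  }
  cbind(lower, upper, deparse.level = 0)
}

check_bounds <- function(b, centers, what) {
  if (!is.matrix(b) || ncol(b) != 2 || nrow(b) != length(centers)) {
    stop(sprintf("%s bounds must be an n x 2 matrix matching the centers", what),
         call. = FALSE)
  }
  if (any(b[, 2] <= b[, 1])) {
    stop(sprintf("%s bounds must have upper > lower", what), call. = FALSE)
  }
  if (nrow(b) > 1 && any(abs(b[-nrow(b), 2] - b[-1, 1]) > 1e-8)) {
    stop(sprintf("%s bounds must tile the domain contiguously", what), call. = FALSE)
  }
  invisible(b)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
              length(x$lat), length(x$lon),
              min(x$lat_bounds), max(x$lat_bounds),
              min(x$lon_bounds), max(x$lon_bounds)))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
n_cells <- function(grid) length(grid$lat) * length(grid$lon)

#' Cell table for a grid
#'
#' Enumerates all cells of a grid with their center coordinates and an area
#' weight proportional to true spherical cell area,
#' `(sin(lat_ub) - sin(lat_lb)) * dlon` — i.e. ~ `cos(lat)` for a uniform grid.
#'
#' @param grid A `grid_spec`.
#' @return A tibble with columns `cell`, `lat_index`, `lon_index`, `lat`,
#'   `lon`, `weight`.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  wlat <- sin(grid$lat_bounds[, 2] * pi / 180) - sin(grid$lat_bounds[, 1] * pi / 180)
  wlon <- grid$lon_bounds[, 2] - grid$lon_bounds[, 1]
  tibble::tibble(
    cell = seq_len(nlat * nlon),
    lat_index = rep(seq_len(nlat), times = nlon),
    lon_index = rep(seq_len(nlon), each = nlat),
    lat = rep(grid$lat, times = nlon),
    lon = rep(grid$lon, each = nlat),
    weight = rep(wlat, times = nlon) * rep(wlon, each = nlat)
  )
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$lon, b$lon, tolerance = 1e-9))
}

#' Define breadbasket regions on a grid
#'
#' A `region_set` assigns grid cells to named, non-overlapping regions (the
#' crop-producing "breadbaskets"); the union of all regions is the global
#' breadbasket mask used for global drought area. Regions are given either as
#' lat/lon boxes (cells are assigned by center containment) or as explicit
#' cell index vectors.
#'
#' @param grid A `grid_spec`.
#' @param boxes Named list of numeric vectors `c(lat_min, lat_max, lon_min,
#'   lon_max)`.
#' @param cells Named list of integer cell-index vectors (alternative to
#'   `boxes`; the two may be mixed, names must be distinct).
#' @return An object of class `region_set`: list with `grid`, `cells` (named
#'   list of cell indices), `weights` (per-cell area weights for the full
#'   grid) and `global_cells` (the union).
#' @examples
#' g <- grid_spec(seq(-52.5, 52.5, 15), seq(-172.5, 172.5, 15))
#' rs <- region_set(g, boxes = list(A = c(20, 50, -120, -75),
#'                                  B = c(-40, -10, -75, -30)))
#' names(rs$cells)
#' @export
region_set <- function(grid, boxes = NULL, cells = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  tab <- grid_cells(grid)
  out <- list()
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    if (length(b) != 4) stop("each box needs c(lat_min, lat_max, lon_min, lon_max)", call. = FALSE)
    lon0 <- normalize_lon(b[3]); lon1 <- normalize_lon(b[4])
    inside <- tab$lat >= b[1] & tab$lat <= b[2]
    inside <- inside & if (b[4] - b[3] >= 360) TRUE   # whole-longitude box
      else if (lon0 <= lon1) tab$lon >= lon0 & tab$lon <= lon1
      else tab$lon >= lon0 | tab$lon <= lon1          # box crossing the date line
    out[[nm]] <- tab$cell[inside]
  }
  for (nm in names(cells)) out[[nm]] <- as.integer(cells[[nm]])
  if (length(out) == 0) stop("no regions supplied", call. = FALSE)
  if (anyDuplicated(names(out))) stop("region names must be unique", call. = FALSE)
  nc <- n_cells(grid)
  for (nm in names(out)) {
    idx <- out[[nm]]
    if (length(idx) == 0) stop(sprintf("region '%s' contains no grid cells", nm), call. = FALSE)
    if (any(idx < 1 | idx > nc)) stop(sprintf("region '%s' has cells outside the grid", nm), call. = FALSE)
  }
  all_idx <- unlist(out, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    stop("regions overlap: a cell may belong to at most one region", call. = FALSE)
  }
  structure(
    list(grid = grid, cells = out, weights = tab$weight,
         global_cells = sort(all_idx)),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions on a %d x %d grid\n",
              length(x$cells), length(x$grid$lat), length(x$grid$lon)))
  for (nm in names(x$cells)) cat(sprintf("  %s: %d cells\n", nm, length(x$cells[[nm]])))
  invisible(x)
}

#' @export
names.region_set <- function(x) names(x$cells)

#' Tidy a region set into a cell-membership table
#'
#' @param x A `region_set`.
#' @param ... Unused.
#' @return Tibble with columns `region`, `cell`, `lat`, `lon`, `weight`.
#' @method tidy region_set
#' @export
tidy.region_set <- function(x, ...) {
  tab <- grid_cells(x$grid)
  purrr::map_dfr(names(x$cells), function(nm) {
    dplyr::mutate(tab[x$cells[[nm]], c("cell", "lat", "lon", "weight")],
                  region = nm, .before = 1)
  })
}

region_cells <- function(regions, scope) {
  if (identical(scope, "global")) return(regions$global_cells)
  if (!scope %in% names(regions$cells)) {
    stop(sprintf("unknown scope '%s'; expected 'global' or one of: %s",
                 scope, paste(names(regions$cells), collapse = ", ")), call. = FALSE)
  }
  regions$cells[[scope]]
}

# Overlap matrix between destination and source 1-D bounds, in a measure where
# equal measure means equal spherical area (sin(lat) for latitude, degrees for
# longitude). Rows: destination cells; columns: source cells.
overlap_matrix <- function(dst_bounds, src_bounds, sin_transform = FALSE) {
  f <- if (sin_transform) function(x) sin(x * pi / 180) else identity
  dl <- f(dst_bounds[, 1]); du <- f(dst_bounds[, 2])
  sl <- f(src_bounds[, 1]); su <- f(src_bounds[, 2])
  lo <- outer(dl, sl, pmax)
  hi <- outer(du, su, pmin)
  pmax(hi - lo, 0)
}

#' First-order conservative regridding between lat-lon grids
#'
#' Each destination cell receives the area-overlap-weighted mean of the source
#' cells it intersects, with overlap areas computed analytically on the sphere
#' (latitude measured in sin-latitude). When the source tiles the destination
#' domain, the global area-weighted mean is conserved to numerical precision,
#' and the operation is linear in the field.
#'
#' @param field Numeric matrix `nlat_src x nlon_src` (or a vector of length
#'   `n_cells(src)` in the package's column-major cell order).
#' @param src,dst `grid_spec` objects.
#' @return Matrix `nlat_dst x nlon_dst` of regridded values.
#' @examples
#' src <- grid_spec(c(-45, 45), c(-90, 90))
#' dst <- grid_spec(0, 0, lat_bounds = cbind(-90, 90), lon_bounds = cbind(-180, 180))
#' regrid_conservative(matrix(1:4, 2, 2), src, dst)
#' @export
regrid_conservative <- function(field, src, dst) {
  stopifnot(inherits(src, "grid_spec"), inherits(dst, "grid_spec"))
  if (is.null(dim(field))) field <- matrix(field, length(src$lat), length(src$lon))
  if (!all(dim(field) == c(length(src$lat), length(src$lon)))) {
    stop("field dimensions do not match the source grid", call. = FALSE)
  }
  if (any(!is.finite(field))) stop("field must be finite on the source grid", call. = FALSE)
  o_lat <- overlap_matrix(dst$lat_bounds, src$lat_bounds, sin_transform = TRUE)
  o_lon <- overlap_matrix(dst$lon_bounds, src$lon_bounds, sin_transform = FALSE)
  denom <- outer(rowSums(o_lat), rowSums(o_lon))
  if (any(denom <= 0)) {
    stop("grids do not overlap: some destination cells receive no source area",
         call. = FALSE)
  }
  (o_lat %*% field %*% t(o_lon)) / denom
}

#' Regrid a region mask
#'
#' Regrids a cell-membership indicator conservatively; a destination cell is
#' in-region when at least `threshold` (default 50%) of its area overlaps
#' source region cells.
#'
#' @param cells Integer cell indices of the region on `src`.
#' @param src,dst `grid_spec` objects.
#' @param threshold Area fraction in (0, 1].
#' @return Integer cell indices on `dst`.
#' @export
regrid_mask <- function(cells, src, dst, threshold = 0.5) {
  ind <- numeric(n_cells(src))
  ind[cells] <- 1
  frac <- regrid_conservative(matrix(ind, length(src$lat), length(src$lon)), src, dst)
  which(as.vector(frac) >= threshold)
}
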