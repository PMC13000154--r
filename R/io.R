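#' Write an ensemble cube to CF-style NetCDF
#'
#' Writes dims `(lon, lat, year, member)` (monthly cubes: a `time` axis with
#' auxiliary `year`/`month` variables), cell bounds, the variable's units
#' attribute and the provenance trail as a global attribute, so
#' `load_cube(save_cube(x))` round-trips values and metadata.
#'
#' @param cube A [smile_cube()] or [smile_cube_monthly()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_cube <- function(cube, path) {
  monthly <- inherits(cube, "smile_cube_monthly")
  if (!monthly) stopifnot(inherits(cube, "smile_cube"))
  g <- cube$grid
  nlat <- length(g$lat); nlon <- length(g$lon)
  d <- dim(cube$values)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dim_mem <- ncdf4::ncdim_def("member", "1", seq_len(d[1]))
  dim_bnd <- ncdf4::ncdim_def("bnds", "", 1:2, create_dimvar = FALSE)
  if (monthly) {
    dim_time <- ncdf4::ncdim_def("time", "month index", seq_along(cube$year))
    vars <- list(
      ncdf4::ncvar_def("year", "1", dim_time, prec = "integer"),
      ncdf4::ncvar_def("month", "1", dim_time, prec = "integer")
    )
  } else {
    dim_time <- ncdf4::ncdim_def("year", "calendar year", cube$years)
    vars <- list()
  }
  v_main <- ncdf4::ncvar_def(cube$var_name, cube$units,
                             list(dim_lon, dim_lat, dim_time, dim_mem),
                             missval = 1e30, prec = "double")
  v_latb <- ncdf4::ncvar_def("lat_bnds", "degrees_north", list(dim_bnd, dim_lat))
  v_lonb <- ncdf4::ncvar_def("lon_bnds", "degrees_east", list(dim_bnd, dim_lon))
  nc <- ncdf4::nc_create(path, c(list(v_main, v_latb, v_lonb), vars))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  nt <- d[2]
  # internal (member, time, cell[lat-major]) -> file (lon, lat, time, member)
  arr <- aperm(array(cube$values, c(d[1], nt, nlat, nlon)), c(4, 3, 2, 1))
  ncdf4::ncvar_put(nc, v_main, arr)
  ncdf4::ncvar_put(nc, v_latb, t(g$lat_bounds))
  ncdf4::ncvar_put(nc, v_lonb, t(g$lon_bounds))
  if (monthly) {
    ncdf4::ncvar_put(nc, "year", cube$year)
    ncdf4::ncvar_put(nc, "month", cube$month)
  }
  ncdf4::ncatt_put(nc, 0, "provenance",
                   paste(cube$provenance, collapse = "\n"))
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8 (subset)")
  invisible(path)
}

#' Read an ensemble cube from NetCDF
#'
#' Expects dims `(lon, lat, year|time[, member])`. A file without a `member`
#' dimension is treated as a single-member ensemble with a warning. A monthly
#' time axis (file carries a `month` variable) is annualized only when
#' `annualize = TRUE`; otherwise an error explains the contract.
#'
#' @param path NetCDF file path.
#' @param var_name Variable to read; default: the first variable with a
#'   lat/lon grid.
#' @param annualize Collapse a monthly time axis to calendar-year means.
#' @return A [smile_cube()].
#' @export
load_cube <- function(path, var_name = NULL, annualize = FALSE) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  dn <- names(nc$dim)
  need <- c("lat", "lon")
  if (!all(need %in% dn)) {
    stop(sprintf(paste0("file lacks coordinate variables %s; expected dims ",
                        "(lon, lat, year|time[, member])"),
                 paste(setdiff(need, dn), collapse = ", ")), call. = FALSE)
  }
  if (is.null(var_name)) {
    cand <- names(nc$var)
    cand <- setdiff(cand, c("lat_bnds", "lon_bnds", "year", "month"))
    if (!length(cand)) stop("no data variable found", call. = FALSE)
    var_name <- cand[1]
  }
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat_b <- if ("lat_bnds" %in% names(nc$var)) t(ncdf4::ncvar_get(nc, "lat_bnds")) else NULL
  lon_b <- if ("lon_bnds" %in% names(nc$var)) t(ncdf4::ncvar_get(nc, "lon_bnds")) else NULL
  grid <- grid_spec(lat, lon, lat_bounds = lat_b, lon_bounds = lon_b)
  monthly <- "month" %in% names(nc$var)
  time_dim <- if ("year" %in% dn) "year" else if ("time" %in% dn) "time" else
    stop("file lacks a year/time dimension", call. = FALSE)
  has_member <- "member" %in% dn
  arr <- ncdf4::ncvar_get(nc, var_name, collapse_degen = FALSE)
  var_dims <- vapply(nc$var[[var_name]]$dim, function(d) d$name, character(1))
  perm <- match(c("lon", "lat", time_dim, if (has_member) "member"), var_dims)
  if (anyNA(perm)) stop(sprintf("variable '%s' lacks expected dims", var_name), call. = FALSE)
  arr <- aperm(arr, c(perm, setdiff(seq_along(dim(arr)), perm)))
  nlon <- length(lon); nlat <- length(lat)
  nt <- dim(arr)[3]
  nmem <- if (has_member) dim(arr)[4] else 1L
  if (!has_member) {
    warning("file has no 'member' dimension; treating it as a 1-member ensemble")
    dim(arr) <- c(nlon, nlat, nt, 1L)
  }
  values <- array(aperm(arr, c(4, 3, 2, 1)), c(nmem, nt, nlat * nlon))
  units <- nc$var[[var_name]]$units
  prov_att <- ncdf4::ncatt_get(nc, 0, "provenance")
  prov <- if (isTRUE(prov_att$hasatt) && nzchar(prov_att$value))
    strsplit(prov_att$value, "\n", fixed = TRUE)[[1]] else character()
  if (monthly) {
    yr <- as.integer(ncdf4::ncvar_get(nc, "year"))
    mo <- as.integer(ncdf4::ncvar_get(nc, "month"))
    mc <- smile_cube_monthly(values, yr, mo, grid, units = units,
                             var_name = var_name, provenance = prov)
    if (!annualize) {
      stop("file carries a monthly time axis; pass annualize = TRUE to collapse it",
           call. = FALSE)
    }
    return(annual_mean(mc))
  }
  years <- as.integer(ncdf4::ncvar_get(nc, time_dim))
  smile_cube(values, years, grid, units = units, var_name = var_name,
             provenance = prov)
}

#' Read region masks from a declarative YAML file
#'
#' Schema: a top-level `regions` mapping of region name to either
#' `box: [lat_min, lat_max, lon_min, lon_max]` or `cells: [i, j, ...]`
#' (1-based cell indices in the package's column-major order).
#'
#' @param path YAML file path.
#' @param grid The [grid_spec()] the masks refer to.
#' @return A [region_set()].
#' @export
read_region_config <- function(path, grid) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) stop("region config must have a top-level 'regions' map", call. = FALSE)
  boxes <- list(); cells <- list()
  for (nm in names(cfg$regions)) {
    r <- cfg$regions[[nm]]
    if (!is.null(r$box)) boxes[[nm]] <- as.numeric(r$box)
    else if (!is.null(r$cells)) cells[[nm]] <- as.integer(r$cells)
    else stop(sprintf("region '%s' needs a 'box' or 'cells' entry", nm), call. = FALSE)
  }
  region_set(grid, boxes = boxes, cells = cells)
}
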