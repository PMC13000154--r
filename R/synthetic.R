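#' Configure a synthetic large ensemble
#'
#' Describes a synthetic SMILE: members that differ only through internal
#' variability (a spatially correlated AR(1) Gaussian noise process), plus
#' prescribed per-region long-term changes in the mean and in the standard
#' deviation of annual surface soil moisture. The generator exists so that
#' every downstream stage — drought classification, record statistics,
#' detrending, attribution — can be exercised on data whose truth is known.
#'
#' `mean_trend` entries are functions of calendar year returning the additive
#' offset (soil-moisture units) applied uniformly over the region's cells;
#' `sd_factor` entries return the multiplicative factor (> 0) applied to the
#' noise standard deviation. Cells outside all regions get offset 0 and
#' factor 1. See [ramp_trend()] and [ramp_factor()] for piecewise-linear
#' helpers.
#'
#' @param n_members Ensemble size.
#' @param years Inclusive year range `c(first, last)` (default 1850-2099).
#' @param grid A [grid_spec()].
#' @param regions A [region_set()] on `grid`.
#' @param baseline_mean Scalar or per-cell vector of baseline soil moisture
#'   (default 25 kg m-2, a typical surface value).
#' @param baseline_sd Scalar or per-cell vector of interannual SD (> 0).
#' @param mean_trend Named list (region -> function(year)); missing regions
#'   get zero trend.
#' @param sd_factor Named list (region -> function(year) > 0); missing
#'   regions get factor 1.
#' @param spatial_corr_length e-folding length of the exponential spatial
#'   correlation of the noise, in degrees of great-circle distance
#'   (0 = independent cells).
#' @param ar1_coef Lag-1 autocorrelation of the noise in `[0, 1)`.
#' @param seed Master integer seed; member streams are derived from it by a
#'   counter scheme so earlier members are unchanged when `n_members` grows.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_members, years = c(1850, 2099), grid, regions,
                             baseline_mean = 25, baseline_sd = 1,
                             mean_trend = list(), sd_factor = list(),
                             spatial_corr_length = 0, ar1_coef = 0,
                             seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(regions, "region_set"))
  if (!grids_identical(grid, regions$grid)) stop("regions are not defined on this grid", call. = FALSE)
  n_members <- as.integer(n_members)
  if (n_members < 1) stop("n_members must be >= 1", call. = FALSE)
  years <- as.integer(years)
  stopifnot(length(years) == 2, years[1] <= years[2])
  nc <- n_cells(grid)
  baseline_mean <- recycle_cells(baseline_mean, nc, "baseline_mean")
  baseline_sd <- recycle_cells(baseline_sd, nc, "baseline_sd")
  if (any(baseline_sd <= 0)) stop("baseline_sd must be > 0 everywhere", call. = FALSE)
  check_region_funs(mean_trend, regions, "mean_trend")
  check_region_funs(sd_factor, regions, "sd_factor")
  if (spatial_corr_length < 0) stop("spatial_corr_length must be >= 0", call. = FALSE)
  if (ar1_coef < 0 || ar1_coef >= 1) stop("ar1_coef must lie in [0, 1)", call. = FALSE)
  yrs <- seq(years[1], years[2])
  for (nm in names(sd_factor)) {
    if (any(sd_factor[[nm]](yrs) <= 0)) {
      stop(sprintf("sd_factor for region '%s' must be > 0 for all years", nm), call. = FALSE)
    }
  }
  structure(
    list(n_members = n_members, years = years, grid = grid, regions = regions,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         mean_trend = mean_trend, sd_factor = sd_factor,
         spatial_corr_length = spatial_corr_length, ar1_coef = ar1_coef,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

recycle_cells <- function(x, nc, what) {
  if (length(x) == 1) return(rep(as.numeric(x), nc))
  if (length(x) != nc) stop(sprintf("%s must be scalar or one value per cell", what), call. = FALSE)
  as.numeric(x)
}

check_region_funs <- function(lst, regions, what) {
  bad <- setdiff(names(lst), names(regions$cells))
  if (length(bad)) stop(sprintf("%s names unknown regions: %s", what,
                                paste(bad, collapse = ", ")), call. = FALSE)
  if (length(lst) && !all(vapply(lst, is.function, logical(1)))) {
    stop(sprintf("%s entries must be functions of year", what), call. = FALSE)
  }
  invisible(lst)
}

#' Piecewise-linear trend and scale helpers
#'
#' `ramp_trend(rate, from)` returns a function giving a cumulative mean offset
#' of `rate` units per year starting at year `from` (zero before).
#' `ramp_factor(to, from, until)` returns a function ramping the SD multiplier
#' linearly from 1 at year `from` to `to` at year `until` (held constant
#' outside).
#'
#' @param rate Units per year.
#' @param from,until Calendar years.
#' @param to Final multiplier (> 0).
#' @return A function of year, vectorized.
#' @export
ramp_trend <- function(rate, from) {
  force(rate); force(from)
  function(year) rate * pmax(0, year - from)
}

#' @rdname ramp_trend
#' @export
ramp_factor <- function(to, from, until) {
  force(to); force(from); force(until)
  stopifnot(until > from, to > 0)
  function(year) {
    f <- (pmin(pmax(year, from), until) - from) / (until - from)
    1 + f * (to - 1)
  }
}

# Great-circle central angle between cell centers, in degrees.
central_angle_deg <- function(lat, lon) {
  la <- lat * pi / 180; lo <- lon * pi / 180
  x <- cos(la) * cos(lo); y <- cos(la) * sin(lo); z <- sin(la)
  dot <- tcrossprod(cbind(x, y, z))
  dot <- pmin(pmax(dot, -1), 1)
  acos(dot) * 180 / pi
}

member_seed <- function(seed, member) {
  as.integer((as.double(seed) + as.double(member) * 1000003) %% 2147483629)
}

#' Generate a synthetic large ensemble
#'
#' Draws `value(m, y, c) = baseline_mean(c) + mean_trend(region(c), y) +
#' sd_factor(region(c), y) * baseline_sd(c) * eps(m, y, c)`, where `eps` is a
#' zero-mean unit-variance Gaussian process with exponential spatial
#' correlation `exp(-d / L)` in great-circle degrees and AR(1) persistence in
#' time (applied before the trend/scale injection and initialized from the
#' stationary distribution). Members are independent; identical
#' `(config, seed)` pairs reproduce bit-identical cubes.
#'
#' @param config A [synthetic_config()].
#' @return A [smile_cube()].
#' @examples
#' g <- grid_spec(c(-10, 10), c(-10, 10))
#' rs <- region_set(g, boxes = list(A = c(-20, 20, -20, 20)))
#' cfg <- synthetic_config(3, c(2000, 2010), g, rs, seed = 7)
#' cube <- generate_smile(cfg)
#' dim(cube)
#' @export
generate_smile <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- config$grid
  tab <- grid_cells(g)
  nc <- n_cells(g)
  yrs <- seq(config$years[1], config$years[2])
  ny <- length(yrs)
  nm <- config$n_members

  delta <- matrix(0, ny, nc)
  fac <- matrix(1, ny, nc)
  for (rn in names(config$regions$cells)) {
    idx <- config$regions$cells[[rn]]
    if (!is.null(config$mean_trend[[rn]])) {
      delta[, idx] <- config$mean_trend[[rn]](yrs)
    }
    if (!is.null(config$sd_factor[[rn]])) {
      fac[, idx] <- config$sd_factor[[rn]](yrs)
    }
  }

  L <- config$spatial_corr_length
  chol_u <- NULL
  if (L > 0) {
    corr <- exp(-central_angle_deg(tab$lat, tab$lon) / L)
    chol_u <- chol(corr + diag(1e-10, nc))
  }
  phi <- config$ar1_coef
  innov_scale <- sqrt(1 - phi^2)
  mu <- matrix(config$baseline_mean, ny, nc, byrow = TRUE) + delta
  sd_row <- matrix(config$baseline_sd, ny, nc, byrow = TRUE) * fac

  values <- array(NA_real_, c(nm, ny, nc))
  for (m in seq_len(nm)) {
    set.seed(member_seed(config$seed, m))
    z <- matrix(stats::rnorm(ny * nc), ny, nc)
    if (!is.null(chol_u)) z <- z %*% chol_u
    eps <- z
    if (phi > 0) {
      for (t in 2:ny) eps[t, ] <- phi * eps[t - 1, ] + innov_scale * z[t, ]
    }
    values[m, , ] <- mu + sd_row * eps
  }
  smile_cube(values, yrs, g,
             provenance = sprintf("synthetic SMILE (seed %d, %d members, L=%g deg, phi=%g)",
                                  config$seed, nm, L, phi))
}

#' Stationary counterpart of a synthetic configuration
#'
#' Zeroes all mean trends and pins all SD factors to 1, leaving everything
#' else (grid, regions, noise structure, seed) unchanged — the synthetic
#' analogue of "no long-term trends in soil moisture".
#'
#' @param config A [synthetic_config()].
#' @return A [synthetic_config()] with stationary moments.
#' @export
stationary_variant <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  config$mean_trend <- list()
  config$sd_factor <- list()
  config
}

#' Read a synthetic configuration from YAML
#'
#' Schema: `n_members`, `years: [first, last]`, `seed`, `baseline_mean`,
#' `baseline_sd`, `spatial_corr_length`, `ar1_coef`, a `grid` block with
#' `lat: [start, end, step]` and `lon: [start, end, step]`, a `regions` map as
#' in [read_region_config()], and optional per-region `trends` entries with
#' `rate`/`from` (mean ramp) and `sd_to`/`sd_from`/`sd_until` (SD ramp).
#'
#' @param path YAML file path.
#' @return A [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gs <- cfg$grid
  grid <- grid_spec(seq(gs$lat[1], gs$lat[2], by = gs$lat[3]),
                    seq(gs$lon[1], gs$lon[2], by = gs$lon[3]))
  boxes <- list(); cells <- list()
  for (nm in names(cfg$regions)) {
    r <- cfg$regions[[nm]]
    if (!is.null(r$box)) boxes[[nm]] <- as.numeric(r$box) else cells[[nm]] <- as.integer(r$cells)
  }
  regions <- region_set(grid, boxes = boxes, cells = cells)
  mean_trend <- list(); sd_factor <- list()
  for (nm in names(cfg$trends)) {
    tr <- cfg$trends[[nm]]
    if (!is.null(tr$rate)) mean_trend[[nm]] <- ramp_trend(tr$rate, tr$from)
    if (!is.null(tr$sd_to)) sd_factor[[nm]] <- ramp_factor(tr$sd_to, tr$sd_from, tr$sd_until)
  }
  synthetic_config(
    n_members = cfg$n_members %||% 10L,
    years = as.integer(cfg$years %||% c(1850L, 2099L)),
    grid = grid, regions = regions,
    baseline_mean = cfg$baseline_mean %||% 25,
    baseline_sd = cfg$baseline_sd %||% 1,
    mean_trend = mean_trend, sd_factor = sd_factor,
    spatial_corr_length = cfg$spatial_corr_length %||% 0,
    ar1_coef = cfg$ar1_coef %||% 0,
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
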