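# Independent brute-force oracles. These deliberately use plain loops and
# never call the package functions they are used to check.

oracle_drought_area <- function(mask_arr, years, sel_cells, den_cells, w) {
  d <- dim(mask_arr)
  out <- NULL
  for (m in seq_len(d[1])) {
    for (yi in seq_len(d[2])) {
      num <- 0
      for (cc in sel_cells) if (mask_arr[m, yi, cc]) num <- num + w[cc]
      out <- rbind(out, data.frame(member = m, year = years[yi],
                                   area = 100 * num / sum(w[den_cells])))
    }
  }
  out
}

oracle_record_scan <- function(values, margin) {
  run_max <- values[1]
  hits <- integer()
  for (i in seq_along(values)[-1]) {
    ok <- if (margin > 0) values[i] >= run_max + margin else values[i] > run_max
    if (ok) hits <- c(hits, i)
    if (values[i] > run_max) run_max <- values[i]
  }
  hits
}

oracle_window_prob <- function(event_years, span, window, n_members) {
  h <- (window - 1) / 2
  centers <- span[span - h >= min(span) & span + h <= max(span)]
  data.frame(
    year = centers,
    probability = vapply(centers, function(y) {
      sum(event_years >= y - h & event_years <= y + h) / (window * n_members)
    }, numeric(1))
  )
}

oracle_moving_stats <- function(values_arr, years, window) {
  d <- dim(values_arr)
  h <- (window - 1) / 2
  mu <- sd <- matrix(NA_real_, d[2], d[3])
  for (yi in seq_len(d[2])) {
    lo <- max(1, yi - h); hi <- min(d[2], yi + h)
    for (cc in seq_len(d[3])) {
      pool <- as.vector(values_arr[, lo:hi, cc])
      mu[yi, cc] <- mean(pool)
      sd[yi, cc] <- stats::sd(pool)
    }
  }
  list(mean = mu, sd = sd)
}

oracle_moderate_flags <- function(values, window = 31, pct = 0.8) {
  n <- length(values)
  out <- rep(NA, n)
  for (i in seq_len(n)) {
    if (i >= window) {
      pool <- values[(i - window + 1):i]
      out[i] <- values[i] > stats::quantile(pool, pct, type = 7, names = FALSE)
    }
  }
  out
}

oracle_association <- function(ge, re, half_window, period) {
  ge <- ge[ge$year >= period[1] & ge$year <= period[2], ]
  if (nrow(ge) == 0) return(NA_real_)
  hits <- 0
  for (i in seq_len(nrow(ge))) {
    near <- FALSE
    for (j in seq_len(nrow(re))) {
      if (re$member[j] == ge$member[i] &&
          abs(re$year[j] - ge$year[i]) <= half_window) near <- TRUE
    }
    if (near) hits <- hits + 1
  }
  hits / nrow(ge)
}

oracle_regrid <- function(field, src, dst) {
  sinl <- function(x) sin(x * pi / 180)
  out <- matrix(NA_real_, length(dst$lat), length(dst$lon))
  for (i in seq_along(dst$lat)) {
    for (j in seq_along(dst$lon)) {
      num <- den <- 0
      for (k in seq_along(src$lat)) {
        for (l in seq_along(src$lon)) {
          dlat <- max(0, min(sinl(dst$lat_bounds[i, 2]), sinl(src$lat_bounds[k, 2])) -
                         max(sinl(dst$lat_bounds[i, 1]), sinl(src$lat_bounds[k, 1])))
          dlon <- max(0, min(dst$lon_bounds[j, 2], src$lon_bounds[l, 2]) -
                         max(dst$lon_bounds[j, 1], src$lon_bounds[l, 1]))
          num <- num + dlat * dlon * field[k, l]
          den <- den + dlat * dlon
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

global_weighted_mean <- function(field, grid) {
  w <- matrix(grid_cells(grid)$weight, length(grid$lat), length(grid$lon))
  sum(field * w) / sum(w)
}
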