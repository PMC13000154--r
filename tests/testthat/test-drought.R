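# A cube whose pooled 1850-1899 per-cell sample is exactly {1, ..., 100}:
# 2 members x 50 years, member 1 holding 1..50 and member 2 holding 51..100.
pooled_1_to_100_cube <- function() {
  vals <- array(NA_real_, c(2, 50, 1))
  vals[1, , 1] <- 1:50
  vals[2, , 1] <- 51:100
  series_cube(matrix(vals, 2, 50), years = 1850:1899)
}

test_that("pooled percentile thresholds use linear order-statistic interpolation", {
  cube <- pooled_1_to_100_cube()
  b20 <- fit_baseline(cube, ref_period = c(1850, 1899), percentile = 20)
  expect_equal(b20$stats$threshold, 20.8)
  b5 <- fit_baseline(cube, ref_period = c(1850, 1899), percentile = 5)
  expect_equal(b5$stats$threshold, 5.95)
  expect_equal(b20$stats$mean, mean(1:100))
  expect_equal(b20$stats$sd, sd(1:100))
  expect_equal(glance(b20)$n_pooled, 100)
  expect_error(fit_baseline(cube, percentile = 0), "percentile")
  expect_error(fit_baseline(cube, percentile = 100), "percentile")
})

test_that("a constant pooled sample yields a degenerate, flagged baseline", {
  cube <- series_cube(matrix(4, 2, 10), years = 1850:1859)
  b <- fit_baseline(cube, ref_period = c(1850, 1859))
  expect_equal(b$stats$threshold, 4)
  expect_equal(b$stats$sd, 0)
  expect_true(b$stats$degenerate)
})

test_that("drought classification is strictly below the threshold", {
  cube <- pooled_1_to_100_cube()
  b <- fit_baseline(cube, percentile = 20)
  probe <- series_cube(matrix(c(20.8, 20.8 - 1e-9), 1, 2), years = 1850:1851)
  m <- classify_drought(probe, b)
  expect_false(m$mask[1, 1, 1])   # at the threshold: not drought
  expect_true(m$mask[1, 2, 1])    # just below: drought
  # pooled drought frequency on the reference sample itself is ~p%
  mask_ref <- classify_drought(cube, b)
  expect_equal(mean(mask_ref$mask), 0.20, tolerance = 0.01)
})

test_that("grid mismatches raise a geometry error", {
  cube <- tiny_cube(2, c(1850, 1899))
  other <- tiny_cube(2, c(1850, 1899), grid = tiny_grid(3, 3),
                     regions = region_set(tiny_grid(3, 3), cells = list(A = 1:9)))
  b <- fit_baseline(other)
  expect_error(classify_drought(cube, b), "grid")
})

test_that("drought area handles both denominators with correct arithmetic", {
  g <- grid_spec(c(-7.5, 7.5), c(0, 15, 30, 45))  # 8 equal-ish cells
  rs <- region_set(g, cells = list(A = 1:4, B = 5:8))
  mask <- random_mask(g, 1, 2000, p = 0)
  mask$mask[1, 1, c(1, 2)] <- TRUE                 # 2 of 4 cells of A
  a_reg <- drought_area(mask, rs, scope = "A", denominator = "regional",
                        equal_weights = TRUE)
  expect_equal(a_reg$area, 50)
  a_glob <- drought_area(mask, rs, scope = "A", denominator = "global",
                         equal_weights = TRUE)
  expect_equal(a_glob$area, 25)
  # a region holding 25% of breadbasket weight, fully in drought
  rs2 <- region_set(g, cells = list(A = 1:2, B = 3:8))
  mask$mask[1, 1, ] <- c(TRUE, TRUE, rep(FALSE, 6))
  expect_equal(drought_area(mask, rs2, scope = "A", denominator = "global",
                            equal_weights = TRUE)$area, 25)
  expect_error(drought_area(mask, rs, scope = "Nowhere"), "unknown scope")
})

test_that("drought area matches the per-cell loop oracle exactly", {
  g <- tiny_grid(3, 4)
  rs <- tiny_regions(g)
  mask <- random_mask(g, 3, 2000:2004, p = 0.4, seed = 9)
  w <- rs$weights
  for (sc in c("A", "B", "global")) {
    got <- drought_area(mask, rs, scope = sc)
    sel <- if (sc == "global") rs$global_cells else rs$cells[[sc]]
    den <- if (sc == "global") rs$global_cells else sel
    want <- oracle_drought_area(mask$mask, mask$years, sel, den, w)
    merged <- merge(got, want, by = c("member", "year"))
    expect_equal(merged$area.x, merged$area.y)
  }
})

test_that("regional global-denominator series sum to the global series", {
  g <- tiny_grid()
  rs <- tiny_regions(g)
  mask <- random_mask(g, 4, 1990:2009, p = 0.35, seed = 13)
  parts <- drought_area(mask, rs, scope = c("A", "B"), denominator = "global")
  tot <- drought_area(mask, rs, scope = "global")
  summed <- aggregate(area ~ member + year, parts, sum)
  merged <- merge(summed, tot, by = c("member", "year"))
  expect_lt(max(abs(merged$area.x - merged$area.y)), 1e-9)
})

test_that("drought intensity averages standardized anomalies over drought cells", {
  g <- grid_spec(c(0, 15), c(0, 15))
  rs <- region_set(g, cells = list(A = 1:4))
  base_cube <- generate_smile(synthetic_config(4, c(1850, 1899), g, rs, seed = 3))
  b <- fit_baseline(base_cube)
  # every cell exactly 1 sigma below its pooled mean -> intensity -1
  probe <- smile_cube(aperm(array(b$stats$mean - b$stats$sd, c(4, 1, 2)),
                            c(2, 3, 1)), 2000:2001, g)
  m <- classify_drought(probe, b)
  expect_true(all(m$mask))
  ii <- drought_intensity(probe, m, b, rs)
  expect_equal(ii$intensity, c(-1, -1))
  # no drought cells -> NA, not zero
  wet <- smile_cube(aperm(array(b$stats$mean + 5, c(4, 1, 1)), c(2, 3, 1)),
                    2000, g)
  mw <- classify_drought(wet, b)
  expect_true(is.na(drought_intensity(wet, mw, b, rs)$intensity))
})

test_that("intensity matches a weighted-mean loop oracle with unequal weights", {
  g <- tiny_grid(3, 3)
  rs <- region_set(g, cells = list(A = 1:9))
  cube <- generate_smile(synthetic_config(3, c(1850, 1910), g, rs, seed = 6))
  b <- fit_baseline(cube, ref_period = c(1850, 1899))
  m <- classify_drought(cube, b)
  got <- drought_intensity(cube, m, b, rs)
  w <- rs$weights
  for (row in c(5, 40, 100)) {
    mem <- got$member[row]; yi <- match(got$year[row], cube$years)
    sel <- which(m$mask[mem, yi, ])
    if (length(sel) == 0) {
      expect_true(is.na(got$intensity[row]))
    } else {
      z <- (cube$values[mem, yi, sel] - b$stats$mean[sel]) / b$stats$sd[sel]
      expect_equal(got$intensity[row], sum(w[sel] * z) / sum(w[sel]))
    }
  }
})

test_that("zero baseline SD on a drought cell raises a computation error", {
  g <- grid_spec(0, 0)
  rs <- region_set(g, cells = list(A = 1L))
  const <- series_cube(matrix(5, 2, 50), years = 1850:1899)
  b <- fit_baseline(const)
  probe <- series_cube(matrix(4, 1, 2), years = 2000:2001)
  m <- classify_drought(probe, b)
  expect_error(drought_intensity(probe, m, b, rs), "SD is zero")
})

test_that("lowering the percentile never increases drought area", {
  cube <- tiny_cube(5, c(1850, 1999), seed = 31)
  rs <- tiny_regions()
  b20 <- fit_baseline(cube, percentile = 20)
  b5 <- fit_baseline(cube, percentile = 5)
  a20 <- drought_area(classify_drought(cube, b20), rs, scope = "global")
  a5 <- drought_area(classify_drought(cube, b5), rs, scope = "global")
  expect_true(all(a5$area <= a20$area + 1e-12))
})
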