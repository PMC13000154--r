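test_that("moderate-drought flags use the strict trailing-window percentile rule", {
  # trailing values 1..31, current = 31: p80 = 25 -> moderately extreme
  area <- tibble::tibble(member = 1, year = 1970:2000, area = 1:31)
  expect_true(is_moderately_extreme(area, member = 1, year = 2000))
  # current value equal to the trailing p80 -> strict ">" says no
  const <- tibble::tibble(member = 1, year = 1970:2000, area = rep(4, 31))
  expect_false(is_moderately_extreme(const, member = 1, year = 2000))
  # current value is the trailing-window minimum -> no
  dipped <- tibble::tibble(member = 1, year = 1970:2000, area = c(2:31, 1))
  expect_false(is_moderately_extreme(dipped, member = 1, year = 2000))
  expect_error(is_moderately_extreme(area, member = 1, year = 1990),
               "insufficient history")
})

test_that("vectorized moderate flags match the loop oracle per member", {
  set.seed(41)
  area <- tidyr::expand_grid(scope = c("A", "B"), member = 1:3,
                             year = 1950:2049) |>
    dplyr::mutate(area = runif(dplyr::n(), 0, 50))
  flags <- moderate_drought_flags(area, window = 31)
  for (sc in c("A", "B")) for (m in 1:3) {
    v <- area$area[area$scope == sc & area$member == m]
    want <- oracle_moderate_flags(v, 31, 0.8)
    got <- flags$moderate[flags$scope == sc & flags$member == m]
    expect_equal(got, want[!is.na(want)])
  }
  expect_equal(min(flags$year), 1980)   # first year with a full trailing window
})

test_that("coincidence categories partition the global events", {
  ge <- tibble::tibble(member = c(1, 1, 2), year = c(2010, 2040, 2060))
  # each global event co-occurs with exactly two flagged regions
  rf <- tibble::tibble(
    scope = c("USA", "Brazil", "Europe", "India", "USA", "China"),
    member = c(1, 1, 1, 1, 2, 2),
    year = c(2010, 2010, 2040, 2040, 2060, 2060)
  )
  tab <- classify_global_events(ge, rf, period = c(2000, 2099),
                                regions = c("USA", "Brazil", "Argentina",
                                            "Europe", "China", "India"))
  expect_equal(tab$fraction[tab$category == "2 regions"], 100)
  expect_equal(sum(tab$fraction), 100)
  expect_equal(attr(tab, "n_global_events"), 3)
})

test_that("single-region events split into highlighted and Rest categories", {
  ge <- tibble::tibble(member = 1:4, year = rep(2050, 4))
  rf <- tibble::tibble(scope = c("Europe", "USA", "India"),
                       member = c(1, 2, 3), year = rep(2050, 3))
  tab <- classify_global_events(ge, rf, regions = c("USA", "Brazil", "Argentina",
                                                    "Europe", "China", "India"))
  frac <- function(cat) tab$fraction[tab$category == cat]
  expect_equal(frac("Europe only"), 25)
  expect_equal(frac("USA only"), 25)
  expect_equal(frac("Rest only"), 25)   # India is not highlighted
  expect_equal(frac("0 regions"), 25)
  expect_equal(sum(tab$fraction), 100)
})

test_that("random coincidence tables match the exhaustive counting oracle", {
  set.seed(77)
  regions <- c("USA", "Brazil", "Argentina", "Europe", "China", "India")
  for (rep_i in 1:10) {
    ge <- tibble::tibble(member = sample(1:5, 12, TRUE),
                         year = sample(2000:2099, 12, TRUE))
    rf <- tibble::tibble(scope = sample(regions, 60, TRUE),
                         member = sample(1:5, 60, TRUE),
                         year = sample(2000:2099, 60, TRUE)) |>
      dplyr::distinct()
    tab <- classify_global_events(ge, rf, regions = regions)
    expect_equal(sum(tab$fraction), 100)
    # oracle: count flagged regions per event
    for (i in seq_len(nrow(ge))) {
      k <- length(unique(rf$scope[rf$member == ge$member[i] &
                                    rf$year == ge$year[i]]))
      cat_i <- if (k == 0) "0 regions"
        else if (k == 1) {
          r <- unique(rf$scope[rf$member == ge$member[i] & rf$year == ge$year[i]])
          if (r %in% c("Europe", "USA", "Brazil")) paste(r, "only") else "Rest only"
        } else paste(k, "regions")
      expect_gte(tab$n_events[tab$category == cat_i], 1)
    }
    # totals agree with brute-force tabulation
    ks <- vapply(seq_len(nrow(ge)), function(i) {
      length(unique(rf$scope[rf$member == ge$member[i] & rf$year == ge$year[i]]))
    }, integer(1))
    expect_equal(sum(tab$n_events[grepl("regions$", tab$category) &
                                    tab$category != "0 regions"]),
                 sum(ks >= 2))
    expect_equal(tab$n_events[tab$category == "0 regions"], sum(ks == 0))
  }
})

test_that("zero global events yield an explicit empty status, never NaN", {
  ge <- tibble::tibble(member = 1, year = 1900)   # outside the period
  rf <- tibble::tibble(scope = "USA", member = 1, year = 2050)
  tab <- classify_global_events(ge, rf, period = c(2000, 2099))
  expect_identical(attr(tab, "status"), "no-global-events")
  expect_equal(nrow(tab), 0)
  expect_false(any(is.nan(tab$fraction)))
})

test_that("coincidence fractions are invariant to member relabeling", {
  set.seed(13)
  ge <- tibble::tibble(member = sample(1:4, 10, TRUE),
                       year = sample(2000:2099, 10, TRUE))
  rf <- tibble::tibble(scope = sample(c("A", "B", "C"), 30, TRUE),
                       member = sample(1:4, 30, TRUE),
                       year = sample(2000:2099, 30, TRUE)) |> dplyr::distinct()
  perm <- c(3, 1, 4, 2)
  tab1 <- classify_global_events(ge, rf, regions = c("A", "B", "C"),
                                 highlight = character())
  tab2 <- classify_global_events(
    dplyr::mutate(ge, member = perm[.data$member]),
    dplyr::mutate(rf, member = perm[.data$member]),
    regions = c("A", "B", "C"), highlight = character())
  expect_equal(tab1$fraction, tab2$fraction)
})

test_that("windowed association counts regional events within 15 years only", {
  ge <- tibble::tibble(member = 1, year = 2050)
  re_near <- tibble::tibble(scope = "USA", member = 1, year = 2040)
  re_far <- tibble::tibble(scope = "USA", member = 1, year = 2066)
  expect_equal(windowed_association(ge, re_near)$fraction, 1)
  expect_equal(windowed_association(ge, re_far)$fraction, 0)
  # a regional event in another member does not count
  re_other <- tibble::tibble(scope = "USA", member = 2, year = 2050)
  expect_equal(windowed_association(ge, re_other)$fraction, 0)
})

test_that("windowed association matches the brute-force pairwise oracle", {
  set.seed(19)
  for (rep_i in 1:10) {
    ge <- tibble::tibble(member = sample(1:4, 8, TRUE),
                         year = sample(1995:2095, 8, TRUE))
    re <- tibble::tibble(scope = "R1", member = sample(1:4, 20, TRUE),
                         year = sample(1995:2095, 20, TRUE))
    got <- windowed_association(ge, re, half_window = 15,
                                period = c(2000, 2085))
    want <- oracle_association(ge, re, 15, c(2000, 2085))
    if (is.na(want)) expect_true(is.na(got$fraction)) else
      expect_equal(got$fraction, want)
  }
})
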