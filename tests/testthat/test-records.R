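test_that("record scanning follows the running-maximum-plus-margin rule", {
  s <- c(10, 12, 18, 15, 24)
  shatter <- find_record_events(s, margin = 5)
  expect_equal(shatter$year, c(3, 5))
  expect_equal(shatter$exceedance, c(6, 6))
  expect_equal(unique(shatter$type), "record-shattering")
  breaking <- find_record_events(s, margin = 0)
  expect_equal(breaking$year, c(2, 3, 5))
  expect_equal(unique(breaking$type), "record-breaking")
  # margin comparison is inclusive (">= running max + margin")
  expect_equal(find_record_events(c(10, 15), margin = 5)$year, 2)
  # first tracked year is never an event; the running max updates on
  # non-event exceedances too
  expect_equal(nrow(find_record_events(c(100, 50, 60), margin = 0)), 0)
})

test_that("monotone non-increasing series produce no events at any margin", {
  s <- c(30, 30, 25, 20, 20, 10)
  for (m in c(0, 2.5, 5, 7.5)) {
    expect_equal(nrow(find_record_events(s, margin = m)), 0)
  }
})

test_that("record scans agree with the brute-force oracle on random series", {
  set.seed(17)
  for (i in 1:50) {
    s <- cumsum(rnorm(40)) + rnorm(40, sd = 3)
    for (m in c(0, 1, 2.5)) {
      expect_equal(find_record_events(s, margin = m)$year,
                   oracle_record_scan(s, m))
    }
  }
})

test_that("event sets are nested as the margin grows", {
  set.seed(23)
  for (i in 1:40) {
    s <- cumsum(rnorm(60, sd = 2)) + rnorm(60, sd = 4)
    prev <- NULL
    for (m in c(7.5, 5, 2.5, 0)) {
      ev <- find_record_events(s, margin = m)$year
      if (!is.null(prev)) expect_true(all(prev %in% ev))
      prev <- ev
    }
  }
})

test_that("tracking can start later and short series are rejected", {
  s <- c(10, 12, 18, 15, 24)
  late <- find_record_events(s, years = 2000:2004, margin = 0,
                             tracking_start = 2002)
  expect_equal(late$year, 2004)     # max re-initialized at 2002's value 18
  expect_error(find_record_events(5), "at least 2")
  expect_error(find_record_events(s, margin = -1), "margin")
})

test_that("annual probabilities divide window event counts by member-years", {
  events <- tibble::tibble(member = 1:10, year = rep(1980, 10))
  attr(events, "n_members") <- 10
  attr(events, "years") <- c(1950, 2010)
  p <- annual_probability(events, window = 31)
  expect_equal(p$probability[p$year == 1980], 10 / 310)
  expect_equal(min(p$year), 1965)   # only full-window centers by default
  expect_equal(max(p$year), 1995)
  # no events anywhere -> all-zero curve
  none <- tibble::tibble(member = integer(), year = integer())
  expect_true(all(annual_probability(none, years = c(1950, 2010),
                                     n_members = 5)$probability == 0))
})

test_that("truncated edge mode divides by the clipped window length", {
  events <- tibble::tibble(member = c(1, 2), year = c(1950, 1951))
  p <- annual_probability(events, years = c(1950, 2000), n_members = 4,
                          window = 31, edges = "truncated")
  expect_equal(min(p$year), 1950)
  expect_equal(p$probability[p$year == 1950], 2 / (16 * 4))
})

test_that("annual probabilities match the window-counting oracle", {
  set.seed(5)
  n_mem <- 6
  span <- 1900:1999
  events <- tibble::tibble(
    member = rep(1:n_mem, each = 8),
    year = sample(span, 8 * n_mem, replace = TRUE)
  )
  got <- annual_probability(events, years = range(span), n_members = n_mem,
                            window = 21)
  want <- oracle_window_prob(events$year, span, 21, n_mem)
  expect_equal(got$year, want$year)
  expect_equal(got$probability, want$probability)
})

test_that("at-least-one probabilities are member fractions, monotone in the period", {
  events <- tibble::tibble(member = c(1:12, 1:4), year = c(rep(2030, 12), rep(2070, 4)))
  attr(events, "n_members") <- 40
  attr(events, "years") <- c(1850, 2099)
  expect_equal(prob_at_least_one(events, c(2026, 2055)), 0.30)
  expect_equal(prob_at_least_one(events, c(2026, 2099)), 0.30)  # same members
  events2 <- tibble::tibble(member = c(1:12, 13:16), year = c(rep(2030, 12), rep(2070, 4)))
  attr(events2, "n_members") <- 40
  attr(events2, "years") <- c(1850, 2099)
  p1 <- prob_at_least_one(events2, c(2026, 2055))
  p2 <- prob_at_least_one(events2, c(2026, 2099))
  expect_gte(p2, p1)
  expect_equal(p2, 0.4)
  all_hit <- tibble::tibble(member = 1:7, year = 2030)
  expect_equal(prob_at_least_one(all_hit, c(2026, 2055), n_members = 7), 1)
  expect_error(prob_at_least_one(events, c(1800, 2055)), "outside")
})

test_that("multi-model summaries report the unweighted mean and range", {
  s <- multimodel_summary(c(0.32, 0.80, 0.52))
  expect_equal(s$mean, 0.5466667, tolerance = 1e-6)
  expect_equal(c(s$min, s$max), c(0.32, 0.80))
  one <- multimodel_summary(0.4)
  expect_equal(c(one$mean, one$min, one$max), c(0.4, 0.4, 0.4))
  set.seed(2); v <- runif(7)
  s2 <- multimodel_summary(v)
  expect_equal(s2$mean, sum(v) / 7)
})

test_that("record_events scans every member of an area table", {
  area <- tibble::tibble(
    member = rep(1:2, each = 5),
    year = rep(2000:2004, 2),
    area = c(10, 12, 18, 15, 24, 5, 4, 3, 2, 1)
  )
  ev <- record_events(area, margin = 5)
  expect_equal(ev$member, c(1, 1))
  expect_equal(ev$year, c(2002, 2004))
  expect_equal(attr(ev, "n_members"), 2)
  expect_equal(attr(ev, "years"), c(2000, 2004))
})
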