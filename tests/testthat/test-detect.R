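test_that("baseline threshold uses the pooled linear-interpolation quantile", {
  s <- make_series(0:99)
  w <- period_window("baseline", 2000, 2000)
  expect_equal(baseline_threshold(s, w, 0.95)$value, 94.05)
  # order invariance: permuting the days leaves the threshold unchanged
  set.seed(1)
  s2 <- make_series(sample(0:99))
  expect_equal(baseline_threshold(s2, w, 0.95)$value, 94.05)
  # degenerate distribution
  expect_equal(baseline_threshold(make_series(rep(25, 50)), w, 0.95)$value, 25)
  # a single-day series yields that day's value for any q
  one <- make_series(17.3)
  expect_equal(baseline_threshold(one, w, 0.05)$value, 17.3)
  expect_equal(baseline_threshold(one, w, 0.95)$value, 17.3)
  # window coverage is enforced, naming missing years
  expect_error(baseline_threshold(s, period_window("baseline", 2000, 2002)),
               "missing year")
})

test_that("detect_events finds exactly the maximal strict-exceedance runs", {
  thr <- make_threshold(30)
  ev <- detect_events(make_series(c(31, 32, 33, 29, 31, 31, 29)), thr, 3)
  expect_equal(nrow(ev), 1)  # the trailing 2-day run is not an event
  expect_equal(ev$start_doy, 1)
  expect_equal(ev$duration, 3)
  expect_equal(ev$temps[[1]], c(31, 32, 33))

  # equality is not exceedance
  expect_equal(nrow(detect_events(make_series(rep(30, 4)), thr, 3)), 0)

  # a long run is one event, never split
  ev10 <- detect_events(make_series(c(29, rep(31, 10), 29)), thr, 3)
  expect_equal(nrow(ev10), 1)
  expect_equal(ev10$duration, 10)

  # city/variable mismatch between series and threshold is rejected
  expect_error(detect_events(make_series(31:35, city_id = "Y"), thr, 3),
               "threshold is for")
})

test_that("detection matches the exhaustive maximal-run oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(10:45, 1)
    vals <- round(rnorm(n, 30, 2), 1)
    thr_val <- round(rnorm(1, 30, 1), 1)
    mind <- sample(1:4, 1)
    got <- detect_events(make_series(vals), make_threshold(thr_val), mind)
    want <- brute_force_events(vals, thr_val, mind)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_idx, want$start)
      expect_equal(got$start_idx + got$duration - 1L, want$end)
    }
  }
})

test_that("raising the threshold never increases any index", {
  set.seed(7)
  vals <- round(rnorm(400, 28, 4), 1)
  s <- make_series(vals)
  lo <- annual_indices(detect_events(s, make_threshold(29), 3), s, 2000)
  hi <- annual_indices(detect_events(s, make_threshold(31), 3), s, 2000)
  expect_lte(hi$hwn, lo$hwn)
  expect_lte(hi$hwtd, lo$hwtd)
  expect_lte(hi$hwld, lo$hwld)
  if (!is.na(hi$hht) && !is.na(lo$hht)) expect_lte(hi$hht, lo$hht)
})

test_that("appending sub-threshold days changes no event", {
  vals <- c(29, 31, 32, 33, 29)
  a <- detect_events(make_series(vals), make_threshold(30), 3)
  b <- detect_events(make_series(c(vals, 25, 24, 23)), make_threshold(30), 3)
  expect_equal(a$start_idx, b$start_idx)
  expect_equal(a$duration, b$duration)
})

test_that("annual indices reproduce the two-event worked example", {
  # two events in one year: temps (31,32,33) and (31,31,32,34), threshold 30
  vals <- c(20, 31, 32, 33, 20, 20, 31, 31, 32, 34, 20)
  s <- make_series(vals)
  ev <- detect_events(s, make_threshold(30), 3)
  rec <- annual_indices(ev, s, 2000)
  expect_equal(rec$hwn, 2L)
  expect_equal(rec$hwtd, 7L)
  expect_equal(rec$hwld, 4L)
  expect_equal(rec$hwmt, 32.0)
  expect_equal(rec$hht, 34)

  # event-free year: zero counts, missing intensities
  calm <- make_series(rep(20, 400))
  rec0 <- annual_indices(detect_events(calm, make_threshold(30), 3), calm, 2000)
  expect_equal(rec0$hwn, 0L)
  expect_equal(rec0$hwtd, 0L)
  expect_equal(rec0$hwld, 0L)
  expect_true(is.na(rec0$hwmt) && is.na(rec0$hht))

  # single 5-day event: HWLD = HWTD = 5
  one <- make_series(c(20, rep(31, 5), 20))
  rec1 <- annual_indices(detect_events(one, make_threshold(30), 3), one, 2000)
  expect_equal(rec1$hwld, 5L)
  expect_equal(rec1$hwtd, 5L)

  expect_error(annual_indices(ev, s, 1999), "outside series coverage")
})

test_that("year-boundary events split their days by calendar year", {
  # event spanning 30 Dec - 2 Jan: HWN goes to the start year, the days to
  # their own years
  vals <- c(rep(20, 362), 31, 32, 33, 32, 31, rep(20, 360))
  s <- make_series(vals)  # starts 2000, crosses into 2001
  ev <- detect_events(s, make_threshold(30), 3)
  expect_equal(nrow(ev), 1)
  rec <- annual_indices(ev, s, c(2000, 2001))
  expect_equal(rec$hwn, c(1L, 0L))
  expect_equal(rec$hwtd, c(3L, 2L))
  expect_equal(rec$hwld, c(3L, 2L))
  expect_equal(sum(rec$hwtd), ev$duration)
})

test_that("period means average per index with intensity-year bookkeeping", {
  recs <- data.frame(
    city_id = "A", model_id = "M", scenario = "historical",
    diurnal_var = "tasmax", year = 2000:2002,
    hwn = c(2L, 3L, 4L), hwtd = c(6L, 9L, 12L), hwld = c(3L, 4L, 5L),
    hwmt = c(31, NA, 33), hht = c(33, NA, 36))
  w <- period_window("baseline", 2000, 2002)
  pm <- period_mean_indices(recs, w)
  get <- function(ix) pm[pm$index == ix, ]
  expect_equal(get("hwn")$mean, 3.0)
  expect_equal(get("hwn")$n_years, 3L)
  expect_equal(get("hwmt")$mean, 32.0)   # mean over the 2 contributing years
  expect_equal(get("hwmt")$n_years, 2L)
  # all years event-free: intensity mean missing with count 0
  calm <- recs; calm$hwmt <- NA_real_; calm$hht <- NA_real_
  pmc <- period_mean_indices(calm, w)
  expect_true(is.na(pmc[pmc$index == "hwmt", "mean"]))
  expect_equal(pmc[pmc$index == "hwmt", "n_years"], 0L)
  # incomplete window coverage is rejected
  expect_error(period_mean_indices(recs[-1, ], w), "missing window year")
  expect_error(period_mean_indices(recs[0, ], w), "empty")
})
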