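test_that("thermal limit is the spatial maximum of per-cell 99th percentiles", {
  # constant series: the percentile is the constant
  s1 <- list(a = rep(30, 365 * 56))
  expect_equal(thermal_limit(s1, 1950L), 30)
  # two cells: the spatial maximum wins
  s2 <- list(a = rep(31.2, 365 * 56), b = rep(33.5, 365 * 56))
  expect_equal(thermal_limit(s2, 1950L), 33.5)
  # type-7 linear interpolation pinned by hand on one 365-day baseline year:
  # h = (365 - 1) * 0.99 + 1 = 361.36, so p99 = x_(361) + 0.36 * (x_(362) -
  # x_(361)) = 361.36 for the series 1..365. (Equivalently, 101 equally
  # likely values 1..101 give h = 100 exactly, i.e. p99 = 100.)
  expect_equal(thermal_limit(list(a = as.numeric(1:365)), 1950L,
                             baseline_years = 1950L), 361.36)
})

test_that("thermal limit demands full baseline coverage and grows with the range", {
  expect_error(thermal_limit(list(a = rep(20, 100)), 1950L), "missing data")
  expect_error(thermal_limit(list(), 1950L), "missing data")
  set.seed(12)
  ser <- replicate(5, rnorm(365 * 56, 25, 3), simplify = FALSE)
  names(ser) <- letters[1:5]
  t3 <- thermal_limit(ser[1:3], 1950L)
  t5 <- thermal_limit(ser, 1950L)
  expect_gte(t5, t3)
})

test_that("only runs of more than five consecutive exceedance days are events", {
  base <- rep(20, 365)
  x <- base; x[10:14] <- 31  # exactly five days: not an event
  expect_equal(nrow(detect_events(x, 30)), 0L)
  x2 <- base; x2[10:17] <- 31; x2[50:54] <- 35; x2[200:206] <- 30.5
  ev <- detect_events(x2, 30)
  expect_equal(ev$length, c(8L, 7L))
  expect_equal(ev$start, c(10L, 200L))
  expect_equal(nrow(detect_events(base, 30)), 0L)
  # exceedance is strict: days exactly at the limit do not count
  x3 <- base; x3[1:10] <- 30
  expect_equal(nrow(detect_events(x3, 30)), 0L)
})

test_that("event metrics summarise frequency, longest duration and peak intensity", {
  expect_equal(event_metrics(detect_events(rep(0, 10), 1)),
               c(frequency = 0, duration = 0, intensity = 0))
  ev <- tibble::tibble(start = c(1L, 20L), length = c(8L, 7L),
                       max_exceedance = c(1.5, 2.0))
  expect_equal(event_metrics(ev),
               c(frequency = 2, duration = 8, intensity = 2.0))
  ev2 <- tibble::tibble(start = 1L, length = 6L, max_exceedance = 0.1)
  expect_equal(event_metrics(ev2),
               c(frequency = 1, duration = 6, intensity = 0.1))
  # alternative operationalisations
  expect_equal(event_metrics(ev, duration_rule = "total")[["duration"]], 15)
  expect_equal(event_metrics(ev, intensity_rule = "mean")[["intensity"]], 1.75)
})

test_that("detect_events matches the brute-force day scan on random series", {
  set.seed(77)
  for (i in 1:200) {
    x <- rnorm(365, 25, sample(c(1, 3, 6), 1)) +
      cumsum(rnorm(365, 0, 0.3))
    ts <- quantile(x, runif(1, 0.6, 0.99))
    ev <- detect_events(x, ts)
    bf <- brute_force_events(x, ts)
    expect_equal(as.data.frame(ev), bf, ignore_attr = TRUE)
  }
})

test_that("yearly metrics split runs at calendar-year boundaries", {
  x <- rep(10, 365 * 2)
  x[360:371] <- 31  # 12 hot days crossing 31 December
  m <- yearly_event_metrics(x, 30, start_year = 2000L)
  expect_equal(m$frequency, c(1, 1))
  expect_equal(m$duration, c(6, 6))
  # the same days with min_run 7 produce nothing once split
  m7 <- yearly_event_metrics(x, 30, start_year = 2000L, min_run = 7L)
  expect_equal(sum(m7$frequency), 0)
  expect_error(yearly_event_metrics(rep(0, 100), 0), "multiple of 365")
})

test_that("yearly metrics agree with per-year event detection on random series", {
  set.seed(13)
  for (i in 1:25) {
    ny <- sample(2:4, 1)
    x <- rnorm(365 * ny, 24, 4)
    ts <- quantile(x, 0.95)
    m <- yearly_event_metrics(x, ts, start_year = 1990L)
    for (y in seq_len(ny)) {
      seg <- x[((y - 1) * 365 + 1):(y * 365)]
      ref <- event_metrics(detect_events(seg, ts))
      expect_equal(unlist(m[y, c("frequency", "duration", "intensity")]),
                   ref, ignore_attr = TRUE)
    }
  }
})

test_that("baseline maxima take the per-metric maximum over cells and years", {
  z <- tibble::tibble(frequency = 0, duration = 0, intensity = 0)[0, ]
  expect_equal(baseline_maxima(z),
               c(max_frequency = 0, max_duration = 0, max_intensity = 0))
  m <- tibble::tibble(frequency = c(0, 1, 3), duration = c(0, 9, 6),
                      intensity = c(0, 0.5, 0.2))
  expect_equal(baseline_maxima(m),
               c(max_frequency = 3, max_duration = 9, max_intensity = 0.5))
})

test_that("a series can hold events above its own 99th percentile", {
  # two baseline years, 723 days at 20 and a 7-day spell at 40: the type-7
  # p99 is 20, and the spell is a 7-day baseline event above it
  x <- rep(20, 730); x[100:106] <- 40
  ts <- thermal_limit(list(a = x), 1950L, baseline_years = 1950:1951)
  expect_equal(ts, 20)
  m <- yearly_event_metrics(x, ts, start_year = 1950L)
  expect_equal(m$frequency, c(1, 0))
  expect_equal(m$duration[1], 7)
})

test_that("unsuitability requires strictly exceeding a baseline maximum", {
  b <- c(max_frequency = 2, max_duration = 6, max_intensity = 1.0)
  eq <- tibble::tibble(frequency = 2, duration = 6, intensity = 1.0)
  expect_true(climate_suitable(eq, b))
  zero <- tibble::tibble(frequency = 0, duration = 0, intensity = 0)
  expect_true(climate_suitable(zero, b))
  worse <- tibble::tibble(frequency = 3, duration = 6, intensity = 0.5)
  expect_false(climate_suitable(worse, c(max_frequency = 2, max_duration = 10,
                                         max_intensity = 2.0)))
  # any single metric suffices
  expect_false(climate_suitable(tibble::tibble(frequency = 0, duration = 7,
                                               intensity = 0), b))
})

test_that("the ensemble median is a strict majority of binary flags", {
  expect_false(combine_gcms(c(FALSE, FALSE, FALSE, TRUE, TRUE)))
  expect_true(combine_gcms(c(TRUE, TRUE, TRUE, TRUE, TRUE)))
  expect_true(combine_gcms(c(FALSE, FALSE, TRUE, TRUE, TRUE)))
  expect_false(combine_gcms(c(FALSE, FALSE, FALSE)))
  expect_error(combine_gcms(c(TRUE, FALSE)), "odd number")
})

test_that("uniform warming never shrinks duration, event days or intensity", {
  set.seed(41)
  for (i in 1:40) {
    x <- rnorm(365 * 2, 25, 3) + cumsum(rnorm(730, 0, 0.2))
    ts <- quantile(x, 0.97)
    delta <- runif(1, 0.1, 3)
    m0 <- yearly_event_metrics(x, ts)
    m1 <- yearly_event_metrics(x + delta, ts)
    expect_true(all(m1$duration >= m0$duration))
    expect_true(all(m1$intensity >= m0$intensity))
    t0 <- yearly_event_metrics(x, ts, duration_rule = "total")
    t1 <- yearly_event_metrics(x + delta, ts, duration_rule = "total")
    expect_true(all(t1$duration >= t0$duration))
    # frequency is NOT monotone (adjacent runs can merge); it may only
    # change where event days exist at all
    expect_true(all(m1$frequency[t0$duration == 0 & t1$duration == 0] == 0))
  }
})
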