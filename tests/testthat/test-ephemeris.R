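# Lunar ephemeris: event series, intervals, epochs, constants, CSV I/O.

test_that("syzygy instants match independent almanac anchors within 2 h", {
  # Published almanac values (NASA eclipse catalogues / Espenak tables):
  # full and new moons that coincided with well-documented eclipses, plus
  # the 2016-11-14 perigee of the closest full moon since 1948.
  anchors <- tibble::tibble(
    time = as.POSIXct(c("2000-01-21 04:40", "2015-09-28 02:50",
                        "1999-08-11 11:08", "2017-08-21 18:30"), tz = "UTC"),
    kind = c("full_moon", "full_moon", "new_moon", "new_moon")
  )
  for (i in seq_len(nrow(anchors))) {
    ev <- lunar_phase_events(anchors$time[i] - 5 * 86400,
                             anchors$time[i] + 5 * 86400)
    hit <- ev[ev$kind == anchors$kind[i], ]
    expect_equal(nrow(hit), 1)
    expect_lt(abs(as.numeric(hit$time - anchors$time[i], units = "hours")), 2)
  }
})

test_that("apsis instants and distance match the 2016 supermoon perigee", {
  ev <- lunar_apsis_events("2016-11-01", "2016-11-28")
  peri <- ev[ev$kind == "perigee", ]
  expect_equal(nrow(peri), 1)
  published <- as.POSIXct("2016-11-14 11:23", tz = "UTC")  # 356509 km
  expect_lt(abs(as.numeric(peri$time - published, units = "hours")), 6)
  expect_lt(abs(moon_position(published)$distance_km - 356509), 50)
})

test_that("declination stays within the geometric bound and matches
           standstill-year extremes", {
  tt <- seq(as.POSIXct("1998-01-01", tz = "UTC"),
            as.POSIXct("1999-01-01", tz = "UTC"), by = 6 * 3600)
  expect_true(all(abs(lunar_declination(tt)) <= 29))
  # envelope extremes: ~28.72 deg at major epochs, ~18.1-18.6 at minor
  y2006 <- seq(as.POSIXct("2006-01-01", tz = "UTC"),
               as.POSIXct("2006-12-31", tz = "UTC"), by = 3600)
  y2015 <- seq(as.POSIXct("2015-01-01", tz = "UTC"),
               as.POSIXct("2015-12-31", tz = "UTC"), by = 3600)
  max06 <- max(abs(lunar_declination(y2006)))
  max15 <- max(abs(lunar_declination(y2015)))
  expect_equal(max06, 28.72, tolerance = 0.3 / 28.72)
  expect_gt(max06, max15)
  expect_lt(max15, 19)
  # declination is positive at northern standstills
  st <- standstill_events("2006-01-01", "2006-06-30")
  expect_true(all(lunar_declination(st$time[st$kind == "standstill_n"]) > 0))
  expect_true(all(lunar_declination(st$time[st$kind == "standstill_s"]) < 0))
})

test_that("mean same-kind intervals reproduce the three month lengths", {
  ev <- study_events()
  expect_equal(mean_same_kind_interval(ev, "full_moon"), 29.5306,
               tolerance = 0.01 / 29.5306)
  expect_equal(mean_same_kind_interval(ev, "perigee"), 27.5545,
               tolerance = 0.01 / 27.5545)
  expect_equal(mean_same_kind_interval(ev, "standstill_n"), 27.3216,
               tolerance = 0.01 / 27.3216)
  # count of full moons over 75 years ~ span / synodic month
  expect_equal(sum(ev$kind == "full_moon"), 928, tolerance = 1 / 928)
})

test_that("paired kinds strictly alternate and spacings stay in band", {
  ev <- study_events()
  expect_silent(validate_event_series(ev))
  for (pair in list(c("full_moon", "new_moon"), c("perigee", "apogee"),
                    c("standstill_n", "standstill_s"))) {
    sub <- ev[ev$kind %in% pair, ]
    sub <- sub[order(sub$time), ]
    expect_true(all(sub$kind[-1] != sub$kind[-nrow(sub)]))
  }
  gaps <- function(kind) as.numeric(diff(sort(ev$time[ev$kind == kind])),
                                    units = "days")
  expect_true(all(gaps("full_moon") >= 29.2 & gaps("full_moon") <= 29.9))
  expect_true(all(gaps("perigee") >= 24.5 & gaps("perigee") <= 28.7))
  expect_true(all(gaps("standstill_n") >= 27.0 &
                    gaps("standstill_n") <= 27.7))
})

test_that("empty and degenerate windows behave per contract", {
  t0 <- as.POSIXct("2000-06-01", tz = "UTC")
  expect_equal(nrow(lunar_events(t0, t0)), 0)
  expect_error(lunar_events("2000-02-01", "2000-01-01"), "start")
  expect_error(lunar_declination(as.POSIXct("1800-01-01", tz = "UTC")),
               "within")
})

test_that("standstill epochs reproduce the documented major/minor years", {
  ep_major <- standstill_epochs("2015-01-01", "2030-12-31")
  expect_equal(ep_major$year[ep_major$label == "major"], 2025)
  ep_minor <- standstill_epochs("2005-01-01", "2020-12-31")
  expect_equal(ep_minor$year[ep_minor$label == "minor"], 2015)
  # long historical window: consecutive same-label epochs 18-19 years apart
  ep <- standstill_epochs("1955-01-01", "1999-12-31")
  expect_setequal(ep$year[ep$label == "minor"], c(1959, 1978, 1997))
  expect_setequal(ep$year[ep$label == "major"], c(1969, 1987))
  for (lab in c("major", "minor")) {
    yrs <- sort(ep$year[ep$label == lab])
    if (length(yrs) > 1) expect_true(all(diff(yrs) %in% 18:19))
  }
  expect_error(standstill_epochs("2015-01-01", "2020-01-01"), "10 years")
})

test_that("derived constants match their closed forms", {
  dc <- derived_constants()
  val <- function(k) dc$value[dc$constant == k]
  expect_equal(round(val("saros_years"), 2), 18.03)
  expect_equal(round(val("nodal_years"), 2), 18.61)
  expect_equal(round(val("half_nodal_years"), 1), 9.3)
  expect_equal(round(val("lunar_day_hours"), 1), 24.8)
  expect_equal(round(val("semidiurnal_hours"), 1), 12.4)
})

test_that("interval mean is the arithmetic mean of same-kind gaps", {
  t0 <- as.POSIXct("2000-01-01", tz = "UTC")
  ev <- tibble::tibble(time = t0 + c(0, 10, 20) * 86400,
                       kind = "full_moon")
  expect_equal(mean_same_kind_interval(ev, "full_moon"), 10)
  ev2 <- tibble::tibble(time = t0 + c(0, 29.5) * 86400, kind = "perigee")
  expect_equal(mean_same_kind_interval(ev2, "perigee"), 29.5)
  expect_error(mean_same_kind_interval(ev2, "apogee"), "at least 2")
})

test_that("event CSV round-trips losslessly and rejects bad rows", {
  ev <- lunar_phase_events("2000-01-01", "2000-06-30")
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_csv(ev, f)
  back <- read_event_csv(f)
  expect_equal(back$time, ev$time)
  expect_equal(back$kind, ev$kind)
  # empty file -> empty series
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("datetime,kind", f2)
  expect_equal(nrow(read_event_csv(f2)), 0)
  # minute != 00 violates the hour-resolution contract
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,kind", "2000-01-06T18:30Z,new_moon"), f3)
  expect_error(read_event_csv(f3), "full hour")
  # non-monotone same-kind times
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,kind",
               "2000-02-05T13:00Z,new_moon",
               "2000-02-05T13:00Z,new_moon"), f4)
  expect_error(read_event_csv(f4), "duplicate")
})
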