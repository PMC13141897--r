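# Entrainment: segmentation, period estimation, run detection, limits curve.

cohort_events <- local({
  ev <- NULL
  function() {
    if (is.null(ev)) ev <<- lunar_events("1988-01-01", "2003-12-31")
    ev
  }
})

test_that("segmentation finds clean period steps and nothing else", {
  s <- segment_intervals(c(rep(29, 20), rep(25, 20)))
  expect_equal(nrow(s), 2)
  expect_equal(s$end[1], 20)
  expect_true(all(s$consistent))
  s2 <- segment_intervals(rep(28, 15))
  expect_equal(nrow(s2), 1)
  expect_true(s2$consistent)
  # too-short blocks come back as a single inconsistent segment
  s3 <- segment_intervals(c(29, 30, 28))
  expect_equal(nrow(s3), 1)
  expect_false(s3$consistent)
  # i.i.d. noise around a stable mean: no spurious changepoints in >= 90%
  set.seed(42)
  fp <- replicate(200, nrow(segment_intervals(rnorm(40, 29, 1))) - 1)
  expect_gte(mean(fp == 0), 0.9)
})

test_that("period estimation is exact on pure trains and robust to jitter", {
  expect_equal(estimate_period(seq(0, 19) * 29.5)$tau, 29.5, tolerance = 1e-8)
  expect_equal(
    estimate_period(as.Date("2000-01-01") + round(seq(0, 19) * 29.5))$tau,
    29.5, tolerance = 0.02 / 29.5)
  expect_error(estimate_period(seq(0, 4) * 29), "at least 6")
  set.seed(8)
  errs <- replicate(100, {
    on <- round(seq(0, 29) * 28 + rnorm(30))
    estimate_period(on)$tau - 28
  })
  expect_lte(stats::quantile(abs(errs), 0.95), 0.3)
  # origin-shift equivariance
  on <- round(cumsum(c(0, rnorm(25, 29.7, 0.8))))
  expect_equal(estimate_period(on)$tau, estimate_period(on + 1234)$tau)
})

test_that("run detection needs four consecutive locked onsets", {
  ev <- decade_events()
  # six onsets each 1 day before successive full moons -> one run of 6
  rec <- locked_record(ev, "full_moon", n = 6, offset_days = 1)
  runs <- detect_runs(rec, ev, "synodic")
  expect_equal(nrow(runs), 1)
  expect_equal(runs$length, 6)
  expect_equal(runs$locked_kind, "full_moon")
  # onsets are day-resolution (anchored at 00:00), so "1 day before" the
  # event instant lands 1-2 days early in phase
  expect_lt(runs$mean_offset_days, 0)
  expect_gt(runs$mean_offset_days, -3)
  # three locked onsets then a jump: no run
  fm <- sort(ev$time[ev$kind == "full_moon"])[10:12]
  rec3 <- tibble::tibble(
    woman_id = "w1",
    onset = c(as.Date(fm) - 1, as.Date(fm[3]) + c(15, 44, 74))
  )
  runs3 <- detect_runs(rec3, ev, "synodic")
  expect_true(all(runs3$length >= 4))
  expect_false(any(runs3$start_index == 1 & runs3$end_index == 3))
})

test_that("a stable non-zero offset still counts as entrained", {
  ev <- decade_events()
  rec <- locked_record(ev, "new_moon", n = 8, offset_days = 2)
  runs <- detect_runs(rec, ev, "synodic")
  expect_equal(nrow(runs), 1)
  expect_equal(runs$locked_kind, "new_moon")
  expect_lt(runs$mean_offset_days, -1)
  expect_gt(runs$mean_offset_days, -4)
})

test_that("raising the tolerance merges or grows runs, never loses them", {
  ev <- cohort_events()
  cfg <- sim_config(n_women = 1, seed = 3, noise_sd = 0.8, gap_rate = 0,
                    coupling = c(synodic = 1.2, anomalistic = 0,
                                 tropical = 0),
                    zeitgeber_mode = "ephemeris", events = ev,
                    start_date = as.Date("1990-01-01"))
  for (s in 1:5) {
    set.seed(s)
    sw <- simulate_woman(cfg, tau0 = 29 + s / 4, span_years = 10, slope = 0)
    rs <- lapply(c(0.05, 0.1, 0.15), function(tol) {
      detect_runs(sw$record, ev, "synodic", tolerance = tol)
    })
    # every tight-tolerance run overlaps some looser-tolerance run
    for (k in 1:2) {
      a <- rs[[k]]; b <- rs[[k + 1]]
      for (i in seq_len(nrow(a))) {
        expect_true(any(b$start_index <= a$end_index[i] &
                          b$end_index >= a$start_index[i]))
      }
    }
    # and the loosest tolerance covers at least as much as the tightest
    cov <- vapply(rs, function(r) {
      length(unique(unlist(purrr::map2(r$start_index, r$end_index, seq))))
    }, integer(1))
    expect_gte(cov[3], cov[1])
  }
})

test_that("uncoupled records fire runs at the permutation-null rate", {
  ev <- cohort_events()
  cfg0 <- sim_config(n_women = 1, seed = 1, noise_sd = 0.8, gap_rate = 0,
                     coupling = c(synodic = 0, anomalistic = 0, tropical = 0),
                     zeitgeber_mode = "ephemeris", events = ev,
                     aging_slope = 0, aging_slope_sd = 0,
                     start_date = as.Date("1990-01-01"))
  obs_runs <- 0; obs_cyc <- 0; null_runs <- 0; null_cyc <- 0
  set.seed(314)
  for (i in 1:12) {
    tau <- runif(1, 25, 34)
    sw <- simulate_woman(cfg0, woman_id = "u", tau0 = tau, span_years = 8,
                         slope = 0)
    rec <- sw$record
    obs_runs <- obs_runs + nrow(detect_runs(rec, ev, "synodic"))
    obs_cyc <- obs_cyc + nrow(rec) - 1
    # permutation null: shuffle the intervals, rebuild the onsets
    iv <- as.numeric(diff(rec$onset))
    for (p in 1:3) {
      per <- rec
      per$onset <- rec$onset[1] + c(0, cumsum(sample(iv)))
      null_runs <- null_runs + nrow(detect_runs(per, ev, "synodic"))
      null_cyc <- null_cyc + nrow(per) - 1
    }
  }
  obs_rate <- 100 * obs_runs / obs_cyc
  null_rate <- 100 * null_runs / null_cyc
  expect_lt(abs(obs_rate - null_rate), 2)
})

test_that("limits curve is 100% for a strongly coupled cohort and the
           widest range follows the nearest cycle", {
  ev <- cohort_events()
  cfg <- sim_config(n_women = 8, seed = 21, noise_sd = 0.3, gap_rate = 0,
                    record_span_years = c(6, 8),
                    coupling = c(synodic = 2.5, anomalistic = 0,
                                 tropical = 0),
                    zeitgeber_mode = "ephemeris", events = ev,
                    aging_slope = 0, aging_slope_sd = 0,
                    start_date = as.Date("1990-01-01"))
  coh <- simulate_cohort(cfg)
  curve <- entrainment_limits(coh$records, ev, cycles = "synodic")
  expect_true(all(curve$percent_entrained == 100))
  expect_true(all(curve$n_episodes > 0))
  # empty bins are absent, not zero
  expect_false(any(curve$n_episodes == 0))
})

test_that("curve episodes count consistent segments once each", {
  ev <- decade_events()
  # one woman, constant 28-day cycle for 3 years: one episode in bin 28-29
  rec <- periodic_record(n = 40, period = 28, start = as.Date("1996-02-01"))
  curve <- entrainment_limits(rec, ev, cycles = "synodic")
  expect_equal(sum(curve$n_episodes), 1)
  expect_equal(curve$bin_low, 28)
})
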