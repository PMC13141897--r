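# Circular statistics: phase mapping, duplication, Rayleigh/V tests,
# histograms, pooled analysis.

test_that("onset phase is the normalised position between reference events", {
  t0 <- as.POSIXct("2000-01-01 00:00", tz = "UTC")
  period <- 29.53
  ev <- tibble::tibble(
    time = t0 + seq(0, 10) * period * 86400,
    kind = "full_moon"
  )
  # onset at a reference event -> theta = 0
  rec0 <- tibble::tibble(woman_id = "w", onset = as.Date("2000-01-01"))
  expect_equal(onset_phases(rec0, ev)$theta, 0)
  # whole-day onset inside a fractional interval: day 14 of a 29.53-day
  # interval sits at 2*pi*14/29.53
  ev2 <- tibble::tibble(time = t0 + c(0, 29.53) * 86400, kind = "full_moon")
  rec14 <- tibble::tibble(woman_id = "w", onset = as.Date("2000-01-15"))
  expect_equal(onset_phases(rec14, ev2)$theta, 2 * pi * 14 / 29.53)
  # onset a quarter of a 29.53-day interval after the reference -> pi/2
  prev <- as.POSIXct("2000-01-08 00:00", tz = "UTC") - 7.3825 * 86400
  ev3 <- tibble::tibble(time = prev + c(0, 29.53) * 86400, kind = "full_moon")
  rec_q <- tibble::tibble(woman_id = "w", onset = as.Date("2000-01-08"))
  expect_equal(onset_phases(rec_q, ev3)$theta, pi / 2, tolerance = 1e-9)
  # outside coverage errors
  bad <- tibble::tibble(woman_id = "w", onset = as.Date("1999-12-31"))
  expect_error(onset_phases(bad, ev), "coverage")
})

test_that("phase is invariant to a common time translation", {
  ev <- decade_events()
  rec <- periodic_record(n = 12, period = 29, start = as.Date("1997-03-05"))
  th1 <- onset_phases(rec, ev)$theta
  shift <- 13
  ev2 <- ev
  ev2$time <- ev2$time + shift * 86400
  rec2 <- rec
  rec2$onset <- rec2$onset + shift
  th2 <- onset_phases(rec2, ev2)$theta
  expect_equal(th1, th2, tolerance = 1e-9)
})

test_that("axial duplication folds antipodal phases together", {
  expect_equal(double_phase(0), 0)
  expect_equal(double_phase(pi), 0)
  expect_equal(double_phase(pi / 2), pi)
  expect_equal(double_phase(3 * pi / 2), pi)
  th <- runif(50, 0, 2 * pi)
  expect_equal(double_phase(th), double_phase((th + pi) %% (2 * pi)),
               tolerance = 1e-12)
})

test_that("circular mean and resultant length match closed forms", {
  m <- circular_mean_R(rep(1, 10))
  expect_equal(m$S, 1)
  expect_equal(m$mean_direction, 1)
  expect_equal(circular_mean_R(c(0, pi / 2, pi, 3 * pi / 2))$S, 0,
               tolerance = 1e-12)
  m2 <- circular_mean_R(c(0, pi / 2))
  expect_equal(m2$S, sqrt(2) / 2)
  expect_equal(m2$mean_direction, pi / 4)
  expect_error(circular_mean_R(numeric()), "empty")
})

test_that("Rayleigh test detects concentration and respects the null", {
  r <- rayleigh_test(rep(0.5, 10))
  expect_equal(r$S, 1)
  expect_lt(r$p, 0.001)
  even <- seq(0, 2 * pi, length.out = 31)[-31]
  r2 <- rayleigh_test(even)
  expect_lt(r2$S, 1e-10)
  expect_gt(r2$p, 0.9)
  expect_error(rayleigh_test(c(0, 1, 2)), "n >= 4")
  # von Mises kappa = 2 is detected reliably at n = 50
  set.seed(101)
  rej <- replicate(200, rayleigh_test(rvonmises(50, 0, 2))$p < 0.01)
  expect_gte(mean(rej), 0.95)
})

test_that("Rayleigh type-I error is calibrated under the uniform null", {
  set.seed(2024)
  n <- 100; reps <- 10000
  theta <- matrix(runif(n * reps, 0, 2 * pi), nrow = n)
  C <- colMeans(cos(theta)); S <- colMeans(sin(theta))
  R <- n * sqrt(C^2 + S^2)
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("V test is directional: concentrated at mu0 vs antipodal", {
  v1 <- v_test(rep(0, 20), mu0 = 0)
  expect_lt(v1$p, 1e-6)
  v2 <- v_test(rep(pi, 20), mu0 = 0)
  expect_gt(v2$p, 0.99)
  # under a uniform null the p-value is approximately uniform
  set.seed(7)
  ps <- replicate(400, v_test(runif(1000, 0, 2 * pi))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("antipodal bimodality needs duplication to become directional", {
  # equal-weight von Mises mixture at mu and mu + pi: the undoubled
  # distribution looks uniform to the tests, the doubled one is strongly
  # unimodal at 2*mu (doubled-S expectation is I2(kappa)/I0(kappa), ~0.30
  # at kappa = 2)
  set.seed(99)
  reps <- replicate(100, {
    th <- c(rvonmises(100, 0.7, 2), rvonmises(100, 0.7 + pi, 2))
    thd <- double_phase(th)
    c(s_un = circular_mean_R(th)$S,
      s_d = circular_mean_R(thd)$S,
      agree = rayleigh_test(th)$p > 0.05 && rayleigh_test(thd)$p < 0.05 &&
        v_test(thd, mu0 = double_phase(0.7))$p < 0.05)
  })
  expect_lt(mean(reps["s_un", ]), 0.1)
  expect_gt(mean(reps["s_d", ]), 0.25)
  expect_gte(mean(reps["agree", ]), 0.9)
})

test_that("histogram uses 30 equal bins and conserves counts", {
  centers <- (seq_len(30) - 0.5) * 2 * pi / 30
  h <- phase_histogram(centers)
  expect_equal(nrow(h), 30)
  expect_true(all(h$count == 1))
  h2 <- phase_histogram(2 * pi - 1e-9)
  expect_equal(h2$count[30], 1)
  set.seed(3)
  th <- runif(517, 0, 2 * pi)
  expect_equal(sum(phase_histogram(th)$count), 517)
})

test_that("pooled analysis flags entrained cohorts and honours the S
           threshold convention", {
  ev <- decade_events()
  rec <- dplyr::bind_rows(
    locked_record(ev, "full_moon", n = 12, offset_days = 1, woman_id = "a"),
    locked_record(ev, "new_moon", n = 12, offset_days = 1, woman_id = "b")
  )
  res <- pooled_phase_analysis(rec, ev, cycle = "synodic", doubled = TRUE)
  expect_lt(res$rayleigh$p, 1e-6)
  expect_true(res$peaked)
  expect_equal(res$n, 24)
  g <- glance(res)
  expect_equal(g$n, 24)
  expect_true(g$peaked)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_setequal(td$variant, c("uniform", "directed"))
})

test_that("uniform cohorts are rarely flagged", {
  ev <- decade_events()
  set.seed(11)
  # onsets spread uniformly over four years, far more women than cycles
  rec <- tibble::tibble(
    woman_id = paste0("w", seq_len(2000)),
    onset = as.Date("1998-01-01") + sample.int(1460, 2000, replace = TRUE)
  )
  res <- pooled_phase_analysis(rec, ev, cycle = "synodic", doubled = FALSE)
  expect_gt(res$rayleigh$p, 0.001)
  expect_false(res$peaked)
})
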