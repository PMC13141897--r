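# Synthetic circalunar-oscillator cohorts ------------------------------------

#' Simulation configuration for the circalunar oscillator cohort
#'
#' Parameters of the stochastic circle-map model used to generate
#' stand-in cohorts of menses records with known ground truth. Each
#' onset advances the clock by the current free-running period tau(t),
#' corrected by a sinusoidal pull of each lunar cycle toward its target
#' phase, plus Gaussian timing noise:
#' `t[n+1] = t[n] + tau(t[n]) - sum_c A_c * sin(Phi_c(t[n]) - psi_c) + eps`.
#'
#' Defaults emulate the demographic structure of long-term menses
#' diaries: recording starts at age ~N(25.9, 6.4) years, records span
#' 2--37 years (mean ~6), the free-running period starts around 32 days
#' for menarche-age starts and shortens with age (about -0.25 d/year,
#' e.g. 33 to 24.5 days across three decades), cycle-to-cycle noise is
#' under a day, and pregnancies interrupt recording at a low yearly rate.
#'
#' @param n_women Number of records to generate.
#' @param seed Root seed; per-woman substreams are derived by counter.
#' @param record_span_years Length-2 range of record spans (years),
#'   drawn per woman with mean near 6.
#' @param start_age_mean,start_age_sd Age at recording start (years).
#' @param tau0_menarche Free-running period at menarche (days).
#' @param tau_ref_age Age anchor for `tau0_menarche` (years, default 13).
#' @param aging_slope Change of tau with age (days/year, default -0.25);
#'   per-woman slopes jittered with SD `aging_slope_sd`.
#' @param aging_slope_sd SD of per-woman slope jitter (d/y).
#' @param coupling Named numeric: pull amplitude A_c in days per cycle
#'   for `synodic`, `anomalistic`, `tropical`.
#' @param target_phase Named numeric: preferred phase psi_c (radians;
#'   default just under 2*pi, i.e. onsets about one day before the
#'   reference event, the classic phase relation).
#' @param noise_sd Cycle-to-cycle timing noise SD (days).
#' @param gap_rate Pregnancy/interruption rate per woman-year; each gap
#'   pauses recording for 270--420 days.
#' @param zeitgeber_mode `"idealized"` (strictly periodic cycles at the
#'   nominal month lengths) or `"ephemeris"` (phases taken from the
#'   computed event series).
#' @param start_date Calendar date at which cohort recording begins.
#' @param events Optional precomputed `lunar_events` series (required
#'   for `zeitgeber_mode = "ephemeris"` unless computable on the fly).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_women = 50,
                       seed = 1,
                       record_span_years = c(2, 37),
                       start_age_mean = 25.9, start_age_sd = 6.4,
                       tau0_menarche = 32,
                       tau_ref_age = 13,
                       aging_slope = -0.25,
                       aging_slope_sd = 0.05,
                       coupling = c(synodic = 1.5, anomalistic = 0.5,
                                    tropical = 0.5),
                       target_phase = NULL,
                       noise_sd = 0.8,
                       gap_rate = 0.03,
                       zeitgeber_mode = c("idealized", "ephemeris"),
                       start_date = as.Date("1990-01-01"),
                       events = NULL) {
  zeitgeber_mode <- match.arg(zeitgeber_mode)
  cyc <- lunar_cycles()
  coupling <- coupling[cyc$cycle]
  coupling[is.na(coupling)] <- 0
  names(coupling) <- cyc$cycle
  if (is.null(target_phase)) {
    # about one day before the reference event
    target_phase <- 2 * pi * (1 - 1 / cyc$nominal_period)
    names(target_phase) <- cyc$cycle
  }
  stopifnot(noise_sd >= 0, all(coupling >= 0),
            tau0_menarche >= 20, tau0_menarche <= 40)
  structure(
    list(n_women = n_women, seed = seed,
         record_span_years = record_span_years,
         start_age_mean = start_age_mean, start_age_sd = start_age_sd,
         tau0_menarche = tau0_menarche, tau_ref_age = tau_ref_age,
         aging_slope = aging_slope, aging_slope_sd = aging_slope_sd,
         coupling = coupling, target_phase = target_phase,
         noise_sd = noise_sd, gap_rate = gap_rate,
         zeitgeber_mode = zeitgeber_mode, start_date = start_date,
         events = events),
    class = "sim_config"
  )
}

#' Zeitgeber phase of a time point within a lunar cycle
#'
#' @param t_days Numeric vector: days since the simulation origin.
#' @param cycle `"synodic"`, `"anomalistic"` or `"tropical"`.
#' @param mode `"idealized"` (phase advances uniformly at the nominal
#'   period, zero at the origin) or `"ephemeris"` (phase interpolated
#'   between computed reference events).
#' @param origin Calendar date of day 0 (used in ephemeris mode).
#' @param events `lunar_events` series (ephemeris mode).
#' @return Phases in radians, `[0, 2*pi)`.
#' @export
zeitgeber_phase <- function(t_days, cycle = "synodic",
                            mode = c("idealized", "ephemeris"),
                            origin = as.Date("1990-01-01"), events = NULL) {
  mode <- match.arg(mode)
  info <- cycle_info(cycle)
  if (mode == "idealized") {
    return((2 * pi * (t_days / info$nominal_period)) %% (2 * pi))
  }
  if (is.null(events)) stop("ephemeris mode needs an event series",
                            call. = FALSE)
  ref <- sort(events$time[events$kind == info$reference_kind])
  tt <- as.POSIXct(as.character(origin), tz = "UTC") + t_days * 86400
  if (any(tt < ref[1] | tt >= ref[length(ref)])) {
    stop("time outside event-series coverage", call. = FALSE)
  }
  i <- findInterval(as.numeric(tt), as.numeric(ref))
  prev <- as.numeric(ref[i]); nxt <- as.numeric(ref[i + 1])
  (2 * pi * (as.numeric(tt) - prev) / (nxt - prev)) %% (2 * pi)
}

#' Simulate one woman's record from the circle-map oscillator
#'
#' @param config A [sim_config()].
#' @param woman_id Identifier for the generated record.
#' @param tau0 Free-running period at recording start (days); if `NULL`,
#'   derived from the configured menarche period and aging slope at the
#'   woman's start age.
#' @param span_years Record span; if `NULL`, drawn from the configured
#'   range.
#' @param slope Aging slope for this woman (d/y); if `NULL`, jittered
#'   around the configured slope.
#' @return A list with `record` (tibble `woman_id`, `onset`, `tag`) and
#'   `truth` (tibble `onset_index`, `onset`, `tau`, `interval`,
#'   `locked_cycle`): per-onset ground-truth free-running period and the
#'   cycle (if any) whose nominal period the realized intervals track
#'   within 0.5 days for at least 4 consecutive cycles.
#' @export
simulate_woman <- function(config, woman_id = "w1", tau0 = NULL,
                           span_years = NULL, slope = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cyc <- lunar_cycles()
  if (is.null(span_years)) {
    span_years <- min_max_draw(config$record_span_years, mean_target = 6)
  }
  start_age <- stats::rnorm(1, config$start_age_mean, config$start_age_sd)
  start_age <- min(max(start_age, 13), 45)
  if (is.null(slope)) {
    slope <- stats::rnorm(1, config$aging_slope, config$aging_slope_sd)
  }
  if (is.null(tau0)) {
    tau0 <- config$tau0_menarche +
      config$aging_slope * (start_age - config$tau_ref_age) +
      stats::rnorm(1, 0, 1)
    tau0 <- min(max(tau0, 21), 39)
  }
  span_days <- span_years * 365.25
  n_max <- ceiling(span_days / 20) + 2
  # hoist per-cycle constants out of the onset loop
  active <- which(config$coupling > 0)
  amp <- config$coupling[active]
  psi <- config$target_phase[active]
  nomT <- cyc$nominal_period[active]
  ref_num <- lapply(active, function(k) {
    if (config$zeitgeber_mode == "ephemeris") {
      if (is.null(config$events)) stop("ephemeris mode needs an event series",
                                       call. = FALSE)
      as.numeric(sort(config$events$time[
        config$events$kind == cyc$reference_kind[k]]))
    } else NULL
  })
  origin_num <- as.numeric(as.POSIXct(as.character(config$start_date),
                                      tz = "UTC"))
  phase_of <- function(t, j) {
    if (config$zeitgeber_mode == "idealized") {
      return((2 * pi * t / nomT[j]) %% (2 * pi))
    }
    ref <- ref_num[[j]]
    tn <- origin_num + t * 86400
    if (tn < ref[1] || tn >= ref[length(ref)]) {
      stop("time outside event-series coverage", call. = FALSE)
    }
    i <- findInterval(tn, ref)
    (2 * pi * (tn - ref[i]) / (ref[i + 1] - ref[i])) %% (2 * pi)
  }
  t <- 0
  times <- numeric(0); taus <- numeric(0)
  # pregnancy gaps: draw interruption times up-front
  n_gaps <- stats::rpois(1, config$gap_rate * span_years)
  gap_starts <- sort(stats::runif(n_gaps, 0, span_days))
  gap_lens <- stats::runif(n_gaps, 270, 420)
  gaps_used <- rep(FALSE, n_gaps)
  while (t <= span_days && length(times) < n_max) {
    times <- c(times, t)
    tau_t <- tau0 + slope * (t / 365.25)
    tau_t <- min(max(tau_t, 20), 40)
    taus <- c(taus, tau_t)
    pull <- 0
    for (j in seq_along(active)) {
      pull <- pull + amp[j] * sin(phase_of(t, j) - psi[j])
    }
    step <- tau_t - pull + stats::rnorm(1, 0, config$noise_sd)
    step <- max(step, 15)  # physiological floor
    t_next <- t + step
    hit <- which(!gaps_used & gap_starts > t & gap_starts <= t_next)
    if (length(hit)) {
      hit <- hit[1]
      gaps_used[hit] <- TRUE
      t_next <- t_next + gap_lens[hit]
    }
    t <- t_next
  }
  onset_days <- round(times)
  record <- tibble::tibble(
    woman_id = woman_id,
    onset = config$start_date + onset_days,
    tag = NA_character_
  )
  truth <- tibble::tibble(
    onset_index = seq_along(times),
    onset = record$onset,
    t_days = times,   # continuous oscillator state, before day rounding
    tau = taus,
    interval = c(diff(onset_days), NA_real_),
    locked_cycle = truth_locked_cycle(diff(onset_days), cyc)
  )
  list(record = record, truth = truth)
}

# Label each onset with the cycle (if any) whose nominal period the
# realized intervals track within +/-0.5 d for >= 4 consecutive cycles.
#' @noRd
truth_locked_cycle <- function(intervals, cyc = lunar_cycles(),
                               tol = 0.5, min_run = 4) {
  n_on <- length(intervals) + 1
  lab <- rep(NA_character_, n_on)
  for (k in seq_len(nrow(cyc))) {
    close <- abs(intervals - cyc$nominal_period[k]) <= tol
    r <- rle(close)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values & r$lengths >= min_run)) {
      # intervals starts[j]..ends[j] -> onsets starts[j]..ends[j]+1
      idx <- starts[j]:(ends[j] + 1)
      lab[idx] <- ifelse(is.na(lab[idx]), cyc$cycle[k], lab[idx])
    }
  }
  lab
}

#' @noRd
min_max_draw <- function(range, mean_target) {
  lo <- range[1]; hi <- range[2]
  if (lo >= hi) return(lo)
  # left-skewed span distribution: most records short, a few very long
  x <- lo + stats::rgamma(1, shape = 1.6, scale = (mean_target - lo) / 1.6)
  min(x, hi)
}

#' Simulate a cohort of records
#'
#' Generates `config$n_women` records reproducibly: each woman uses a
#' substream seeded by `config$seed` plus her counter, so cohorts are
#' byte-identical across runs and stable under partial regeneration.
#'
#' @param config A [sim_config()].
#' @return A list with `records` (bound tibble of all onsets) and
#'   `truth` (bound tibble with `woman_id` and per-onset ground truth).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_women = 2, seed = 42))
#' head(cohort$records)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_women == 0) {
    return(list(records = tibble::tibble(woman_id = character(),
                                         onset = as.Date(character()),
                                         tag = character()),
                truth = tibble::tibble()))
  }
  out <- purrr::map(seq_len(config$n_women), function(i) {
    set.seed((config$seed * 1000003L + i) %% .Machine$integer.max)
    sw <- simulate_woman(config, woman_id = sprintf("sim%03d", i))
    sw$truth$woman_id <- sw$record$woman_id[1]
    sw
  })
  list(
    records = dplyr::bind_rows(purrr::map(out, "record")),
    truth = dplyr::relocate(dplyr::bind_rows(purrr::map(out, "truth")),
                            "woman_id")
  )
}

#' Write a simulated cohort's truth table to CSV
#' @param truth Truth tibble from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  df <- data.frame(
    woman_id = truth$woman_id,
    onset_index = truth$onset_index,
    tau = truth$tau,
    locked_cycle = ifelse(is.na(truth$locked_cycle), "",
                          truth$locked_cycle)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
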