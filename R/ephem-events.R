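# Lunar event series: syzygies, apsides, standstills ------------------------

.EVENT_KINDS <- c("full_moon", "new_moon", "perigee", "apogee",
                  "standstill_n", "standstill_s")
.KIND_PAIRS <- list(
  c("full_moon", "new_moon"),
  c("perigee", "apogee"),
  c("standstill_n", "standstill_s")
)

#' The three lunar months
#'
#' Reference table of the three lunar cycles the pipeline tests as
#' zeitgebers: the synodic (full/new moon), anomalistic (perigee/apogee)
#' and tropical (declination standstill) months.
#'
#' @return A tibble with columns `cycle`, `reference_kind`, `anti_kind`,
#'   `nominal_period` (days).
#' @examples
#' lunar_cycles()
#' @export
lunar_cycles <- function() {
  tibble::tibble(
    cycle = c("synodic", "anomalistic", "tropical"),
    reference_kind = c("full_moon", "perigee", "standstill_n"),
    anti_kind = c("new_moon", "apogee", "standstill_s"),
    nominal_period = c(29.5306, 27.5545, 27.3216)
  )
}

#' @noRd
cycle_info <- function(cycle) {
  cycle <- match.arg(cycle, lunar_cycles()$cycle)
  dplyr::filter(lunar_cycles(), .data$cycle == !!cycle)
}

#' @noRd
as_instant <- function(x) {
  if (inherits(x, "POSIXct")) {
    out <- lubridate::with_tz(x, "UTC")
  } else if (inherits(x, "Date")) {
    out <- as.POSIXct(as.character(x), tz = "UTC")
  } else if (is.character(x)) {
    out <- lubridate::ymd_hms(x, tz = "UTC", truncated = 3, quiet = TRUE)
    if (any(is.na(out))) stop("unparseable instant: ", x[is.na(out)][1],
                              call. = FALSE)
  } else {
    stop("instants must be POSIXct, Date or ISO-8601 character",
         call. = FALSE)
  }
  check_instant_range(out)
  out
}

#' @noRd
new_event_series <- function(time, kind, start, end) {
  out <- tibble::tibble(time = time, kind = kind)
  out <- dplyr::arrange(out, .data$time)
  attr(out, "coverage") <- c(start = start, end = end)
  class(out) <- c("lunar_events", class(out))
  out
}

#' Coverage window of an event series
#' @param events A `lunar_events` tibble.
#' @return POSIXct vector of length 2 (start, end).
#' @export
event_coverage <- function(events) {
  cov <- attr(events, "coverage")
  if (is.null(cov)) cov <- c(start = min(events$time), end = max(events$time))
  cov
}

#' Validate a lunar event series
#'
#' Checks the structural invariants of an event table: known kinds,
#' strictly increasing times within each kind, same-kind spacing within
#' 24--33 days, and strict alternation between the paired kinds
#' (full/new, perigee/apogee, northern/southern standstill).
#'
#' @param events A tibble with columns `time` (POSIXct) and `kind`.
#' @return The input, invisibly; errors on violation.
#' @export
validate_event_series <- function(events) {
  stopifnot(is.data.frame(events), all(c("time", "kind") %in% names(events)))
  bad <- setdiff(unique(events$kind), .EVENT_KINDS)
  if (length(bad)) stop("unknown event kind: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (k in intersect(.EVENT_KINDS, unique(events$kind))) {
    tt <- sort(events$time[events$kind == k])
    if (anyDuplicated(tt)) stop("duplicate ", k, " times", call. = FALSE)
    gaps <- as.numeric(diff(tt), units = "days")
    if (length(gaps) && (any(gaps < 24) || any(gaps > 33))) {
      stop("same-kind spacing outside [24, 33] days for kind ", k,
           call. = FALSE)
    }
  }
  for (pair in .KIND_PAIRS) {
    sub <- dplyr::arrange(dplyr::filter(events, .data$kind %in% pair),
                          .data$time)
    if (nrow(sub) > 1 && any(sub$kind[-1] == sub$kind[-nrow(sub)])) {
      stop("events of kinds ", paste(pair, collapse = "/"),
           " do not alternate", call. = FALSE)
    }
  }
  invisible(events)
}

# Parabolic refinement of a local extremum at grid index i (hour units).
#' @noRd
parabolic_offset <- function(y_prev, y_mid, y_next) {
  denom <- y_prev - 2 * y_mid + y_next
  ifelse(abs(denom) < .Machine$double.eps, 0,
         0.5 * (y_prev - y_next) / denom)
}

#' Compute a lunar event series
#'
#' Scans the Moon's position on an hourly grid and extracts timestamped
#' events of up to six kinds: syzygies (`full_moon`, `new_moon`) as
#' crossings of the Moon--Sun elongation through 180 and 0 degrees,
#' apsides (`perigee`, `apogee`) as extrema of the geocentric distance,
#' and monthly standstills (`standstill_n`, `standstill_s`) as extrema of
#' the declination. Event instants are refined by interpolation and
#' rounded to the whole hour, matching the hourly resolution of classical
#' printed lunar almanacs.
#'
#' @param start,end Window bounds (Date, POSIXct or ISO-8601 string, UTC).
#' @param kinds Character vector of event kinds to compute (default all six).
#' @return A `lunar_events` tibble with columns `time` (POSIXct UTC, whole
#'   hours) and `kind`, ordered by time, restricted to `[start, end]`.
#' @examples
#' ev <- lunar_events("2000-01-01", "2000-03-01", kinds = "full_moon")
#' @export
lunar_events <- function(start, end, kinds = .EVENT_KINDS) {
  start <- as_instant(start); end <- as_instant(end)
  if (start > end) stop("start must not be after end", call. = FALSE)
  kinds <- match.arg(kinds, .EVENT_KINDS, several.ok = TRUE)
  if (start == end) return(new_event_series(start[0], character(), start, end))

  pad <- 2 * 86400
  lo <- max(.INSTANT_MIN, start - pad)
  hi <- min(.INSTANT_MAX - 3600, end + pad)
  grid <- seq(lo, hi, by = 3600)
  pos <- moon_position(grid)

  times <- list(); kind_out <- list()

  if (any(kinds %in% c("full_moon", "new_moon"))) {
    elong <- (pos$longitude - sun_longitude(grid)) %% 360
    # unwrap: hourly elongation step is ~0.5 degrees, never a full wrap
    step <- ((diff(elong) + 180) %% 360) - 180
    eu <- elong[1] + c(0, cumsum(step))
    k0 <- ceiling(eu[1] / 180); k1 <- floor(eu[length(eu)] / 180)
    for (k in seq(k0, k1)) {
      target <- 180 * k
      i <- findInterval(target, eu)  # eu increasing
      frac <- (target - eu[i]) / (eu[i + 1] - eu[i])
      t_ev <- grid[i] + frac * 3600
      knd <- if (k %% 2 == 0) "new_moon" else "full_moon"
      if (knd %in% kinds) {
        times <- c(times, list(t_ev)); kind_out <- c(kind_out, knd)
      }
    }
  }

  extrema_events <- function(y, kind_max, kind_min) {
    n <- length(y)
    i <- 2:(n - 1)
    is_max <- y[i] >= y[i - 1] & y[i] > y[i + 1]
    is_min <- y[i] <= y[i - 1] & y[i] < y[i + 1]
    max_idx <- i[is_max]
    for (j in i[is_max | is_min]) {
      off <- parabolic_offset(y[j - 1], y[j], y[j + 1])
      t_ev <- grid[j] + off * 3600
      knd <- if (j %in% max_idx) kind_max else kind_min
      if (knd %in% kinds) {
        times <<- c(times, list(t_ev)); kind_out <<- c(kind_out, knd)
      }
    }
  }

  if (any(kinds %in% c("perigee", "apogee"))) {
    extrema_events(-pos$distance_km, "perigee", "apogee")
  }
  if (any(kinds %in% c("standstill_n", "standstill_s"))) {
    extrema_events(pos$declination, "standstill_n", "standstill_s")
  }

  if (!length(times)) return(new_event_series(start[0], character(),
                                              start, end))
  tm <- lubridate::round_date(do.call(c, times), "hour")
  out <- new_event_series(tm, unlist(kind_out), start, end)
  out <- dplyr::filter(out, .data$time >= start, .data$time <= end)
  attr(out, "coverage") <- c(start = start, end = end)
  class(out) <- c("lunar_events", "tbl_df", "tbl", "data.frame")
  validate_event_series(out)
  out
}

#' Syzygy (full/new moon) events
#' @inheritParams lunar_events
#' @return A `lunar_events` tibble of `full_moon`/`new_moon` events.
#' @export
lunar_phase_events <- function(start, end) {
  lunar_events(start, end, kinds = c("full_moon", "new_moon"))
}

#' Apsis (perigee/apogee) events
#' @inheritParams lunar_events
#' @return A `lunar_events` tibble of `perigee`/`apogee` events.
#' @export
lunar_apsis_events <- function(start, end) {
  lunar_events(start, end, kinds = c("perigee", "apogee"))
}

#' Monthly lunar standstill events
#'
#' Monthly extremes of the Moon's declination: the northernmost
#' (`standstill_n`, positive declination) and southernmost
#' (`standstill_s`, negative declination) point of each tropical month.
#'
#' @inheritParams lunar_events
#' @return A `lunar_events` tibble of `standstill_n`/`standstill_s` events.
#' @export
standstill_events <- function(start, end) {
  lunar_events(start, end, kinds = c("standstill_n", "standstill_s"))
}

#' Mean interval between successive events of one kind
#'
#' @param events A `lunar_events` tibble.
#' @param kind One of the six event kinds.
#' @return Mean gap in days (numeric scalar).
#' @examples
#' \donttest{
#' ev <- lunar_phase_events("1950-01-01", "1951-01-01")
#' mean_same_kind_interval(ev, "full_moon")
#' }
#' @export
mean_same_kind_interval <- function(events, kind) {
  kind <- match.arg(kind, .EVENT_KINDS)
  tt <- sort(events$time[events$kind == kind])
  if (length(tt) < 2) {
    stop("need at least 2 events of kind ", kind, call. = FALSE)
  }
  mean(as.numeric(diff(tt), units = "days"))
}

#' Derived long-period lunar constants
#'
#' Constants implied by the canonical month lengths: the Saros
#' eclipse-recurrence cycle (223 synodic months), the 18.61-year nodal
#' cycle (beat of the draconic and tropical months) and its half cycle,
#' and the lunar day with its semidiurnal (tidal) half period.
#'
#' @return A tibble with one row per constant: `constant`, `value`, `unit`.
#' @examples
#' derived_constants()
#' @export
derived_constants <- function() {
  synodic <- 29.5306
  draconic <- 27.212221
  tropical <- 27.321582
  saros_years <- 223 * synodic / 365.25
  nodal_years <- 1 / (1 / draconic - 1 / tropical) / 365.25
  lunar_day_hours <- 24 / (1 - 1 / synodic)
  tibble::tibble(
    constant = c("saros_years", "nodal_years", "half_nodal_years",
                 "lunar_day_hours", "semidiurnal_hours"),
    value = c(saros_years, nodal_years, nodal_years / 2,
              lunar_day_hours, lunar_day_hours / 2),
    unit = c("years", "years", "years", "hours", "hours")
  )
}

#' Major/Minor lunar standstill epochs
#'
#' Tracks the 18.61-year envelope of the monthly extreme lunar
#' declination: monthly maxima of |declination| are smoothed with a
#' centred 13-month moving mean, and interior turning points of the
#' smoothed envelope are reported as Major (peak) or Minor (trough)
#' standstill epochs.
#'
#' @param start,end Window bounds; the span must be at least 10 years for
#'   an extremum of the envelope to be identifiable.
#' @param step_hours Scan step for the declination grid (default 1 hour).
#' @return A tibble with columns `year`, `label` (`"major"`/`"minor"`) and
#'   `envelope_deg` (smoothed |declination| at the epoch).
#' @examples
#' \donttest{
#' standstill_epochs("2015-01-01", "2030-12-31")
#' }
#' @export
standstill_epochs <- function(start, end, step_hours = 1) {
  start <- as_instant(start); end <- as_instant(end)
  if (as.numeric(end - start, units = "days") < 10 * 365.25) {
    stop("window must span at least 10 years", call. = FALSE)
  }
  env <- monthly_declination_envelope(start, end, step_hours)
  s <- env$envelope
  valid <- which(!is.na(s))
  if (!length(valid)) stop("window too short for 13-month smoothing",
                           call. = FALSE)
  margin <- 6   # months kept clear of the valid-range edges
  half <- 56    # ~half of the 9.3-year half-nodal cycle, in months
  interior <- valid[valid > min(valid) + margin & valid < max(valid) - margin]
  years <- integer(); labels <- character(); vals <- numeric()
  for (i in interior) {
    win <- valid[valid >= i - half & valid <= i + half]
    if (s[i] >= max(s[win]) && sum(s[win] == s[i]) == 1) {
      years <- c(years, env$year[i]); labels <- c(labels, "major")
      vals <- c(vals, s[i])
    } else if (s[i] <= min(s[win]) && sum(s[win] == s[i]) == 1) {
      years <- c(years, env$year[i]); labels <- c(labels, "minor")
      vals <- c(vals, s[i])
    }
  }
  tibble::tibble(year = years, label = labels, envelope_deg = vals)
}

# Monthly maxima of |declination| with a centred 13-month moving mean.
#' @noRd
monthly_declination_envelope <- function(start, end, step_hours = 1) {
  grid <- seq(start, end, by = step_hours * 3600)
  dec <- abs(moon_position(grid)$declination)
  month_id <- format(grid, "%Y-%m")
  mx <- tapply(dec, month_id, max)
  months <- sort(names(mx))
  x <- as.numeric(mx[months])
  sm <- stats::filter(x, rep(1 / 13, 13), sides = 2)
  tibble::tibble(
    month = months,
    year = as.integer(substr(months, 1, 4)),
    monthly_max = x,
    envelope = as.numeric(sm)
  )
}

# Event CSV dialect ----------------------------------------------------------

#' Read / write a lunar event CSV
#'
#' The on-disk dialect is a two-column CSV `datetime,kind` with `datetime`
#' an ISO-8601 UTC hour (`YYYY-MM-DDTHH:00Z`) and `kind` one of the six
#' event tokens. Files with minute or second precision are rejected: the
#' series contract is whole-hour resolution.
#'
#' @param path File path.
#' @return `read_event_csv()` returns a validated `lunar_events` tibble;
#'   `write_event_csv()` returns `path` invisibly.
#' @examples
#' \donttest{
#' ev <- lunar_phase_events("2000-01-01", "2000-06-01")
#' f <- tempfile(fileext = ".csv")
#' write_event_csv(ev, f)
#' identical(read_event_csv(f)$time, ev$time)
#' }
#' @export
read_event_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    return(new_event_series(as.POSIXct(character(), tz = "UTC"), character(),
                            .INSTANT_MIN, .INSTANT_MAX))
  }
  if (!all(c("datetime", "kind") %in% names(raw))) {
    stop("event CSV must have columns datetime,kind", call. = FALSE)
  }
  tm <- lubridate::ymd_hms(raw$datetime, tz = "UTC", truncated = 2,
                           quiet = TRUE)
  bad <- which(is.na(tm))
  if (length(bad)) stop("unparseable datetime at line ", bad[1] + 1,
                        call. = FALSE)
  notfull <- which(lubridate::minute(tm) != 0 | lubridate::second(tm) != 0)
  if (length(notfull)) {
    stop("datetime not at a full hour at line ", notfull[1] + 1,
         call. = FALSE)
  }
  out <- new_event_series(tm, raw$kind, min(tm), max(tm))
  validate_event_series(out)
  out
}

#' @rdname read_event_csv
#' @param events A `lunar_events` tibble.
#' @export
write_event_csv <- function(events, path) {
  validate_event_series(events)
  df <- data.frame(
    datetime = format(events$time, "%Y-%m-%dT%H:00Z", tz = "UTC"),
    kind = events$kind
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
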