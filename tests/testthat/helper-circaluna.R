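# Shared fixtures: computed once per test run, lazily.

.fixture_env <- new.env(parent = emptyenv())

# Full six-kind event series 1950-2024 (the study window).
study_events <- function() {
  if (is.null(.fixture_env$events)) {
    .fixture_env$events <- lunar_events("1950-01-01", "2024-12-31")
  }
  .fixture_env$events
}

# Shorter series for record-level tests (1995-2005).
decade_events <- function() {
  if (is.null(.fixture_env$decade)) {
    .fixture_env$decade <- lunar_events("1995-01-01", "2005-12-31")
  }
  .fixture_env$decade
}

# A perfectly periodic record: onsets every `period` days from `start`.
periodic_record <- function(n = 20, period = 29.5,
                            start = as.Date("1997-01-02"),
                            woman_id = "w1") {
  tibble::tibble(
    woman_id = woman_id,
    onset = start + round(seq(0, n - 1) * period),
    tag = NA_character_
  )
}

# Record whose onsets sit a fixed number of days before successive events
# of one kind.
locked_record <- function(events, kind = "full_moon", n = 6, offset_days = 1,
                          from = as.POSIXct("1997-01-01", tz = "UTC"),
                          woman_id = "w1") {
  ev <- sort(events$time[events$kind == kind & events$time >= from])[1:n]
  tibble::tibble(
    woman_id = woman_id,
    onset = as.Date(ev) - offset_days,
    tag = NA_character_
  )
}
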