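# Menses-onset records: I/O, validation, intervals, subsetting --------------

# Interval length (days) above which an inter-onset gap is treated as a
# pregnancy / lactation / missing-data break rather than a cycle.
.DEFAULT_GAP_DAYS <- 60

#' Read menses-onset records
#'
#' Loads per-woman ordered onset dates (and optional birth/miscarriage
#' annotations) from a CSV with columns `woman_id,onset_date[,tag]`, plus
#' an optional metadata CSV `woman_id,country,age_at_start,source_era`.
#' Rows are sorted within woman; duplicate onsets for the same woman are
#' an error. Records spanning less than `min_span_years` are flagged
#' `excluded` (and dropped unless `keep_short = TRUE`), mirroring the
#' usual longitudinal inclusion criterion of at least two years of
#' continuous recording.
#'
#' @param path Records CSV path.
#' @param metadata_path Optional metadata CSV path.
#' @param min_span_years Minimum record span in years (default 2).
#' @param keep_short Keep records shorter than the minimum span, flagged
#'   in the `excluded` column (default `FALSE`: they are dropped with a
#'   warning).
#' @return A `menses_records` tibble with columns `woman_id`, `onset`
#'   (Date), `tag` (NA, `"birth"` or `"miscarriage"`), plus any metadata
#'   columns, and an `excluded` logical column when `keep_short = TRUE`.
#' @export
read_records_csv <- function(path, metadata_path = NULL,
                             min_span_years = 2, keep_short = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("woman_id", "onset_date") %in% names(raw))) {
    stop("records CSV must have columns woman_id,onset_date", call. = FALSE)
  }
  onset <- as.Date(raw$onset_date)
  if (any(is.na(onset))) {
    stop("unparseable onset_date at line ", which(is.na(onset))[1] + 1,
         call. = FALSE)
  }
  rec <- tibble::tibble(
    woman_id = as.character(raw$woman_id),
    onset = onset,
    tag = if ("tag" %in% names(raw)) dplyr::na_if(as.character(raw$tag), "")
          else NA_character_
  )
  rec <- dplyr::arrange(rec, .data$woman_id, .data$onset)
  dup <- dplyr::summarise(dplyr::group_by(rec, .data$woman_id),
                          dup = anyDuplicated(.data$onset) > 0)
  if (any(dup$dup)) {
    stop("duplicate onset for woman ", dup$woman_id[dup$dup][1],
         call. = FALSE)
  }
  span <- dplyr::summarise(
    dplyr::group_by(rec, .data$woman_id),
    span_years = as.numeric(max(.data$onset) - min(.data$onset)) / 365.25
  )
  short <- span$woman_id[span$span_years < min_span_years]
  if (length(short)) {
    if (keep_short) {
      rec$excluded <- rec$woman_id %in% short
    } else {
      warning(length(short), " record(s) span less than ", min_span_years,
              " years and were excluded: ", paste(short, collapse = ", "),
              call. = FALSE)
      rec <- dplyr::filter(rec, !.data$woman_id %in% short)
    }
  } else if (keep_short) {
    rec$excluded <- FALSE
  }
  if (!is.null(metadata_path)) {
    meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    meta$woman_id <- as.character(meta$woman_id)
    rec <- dplyr::left_join(rec, tibble::as_tibble(meta), by = "woman_id")
  }
  class(rec) <- c("menses_records", class(rec))
  rec
}

#' Write menses-onset records to CSV
#' @param records A records tibble (`woman_id`, `onset`, optional `tag`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  df <- data.frame(
    woman_id = records$woman_id,
    onset_date = format(records$onset, "%Y-%m-%d"),
    tag = if ("tag" %in% names(records)) {
      ifelse(is.na(records$tag), "", records$tag)
    } else ""
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inter-onset cycle intervals
#'
#' Successive differences of each woman's onset dates, with a `gap` flag
#' marking intervals longer than `gap_days` (pregnancy, lactation or
#' missing data) that must not be treated as menstrual cycles.
#'
#' @param records A records tibble with `woman_id` and `onset` columns.
#' @param gap_days Gap threshold in days (default 60, about twice the
#'   longest entrainable cycle).
#' @return A tibble with one row per interval: `woman_id`, `start`, `end`,
#'   `length` (integer days), `gap`.
#' @examples
#' rec <- tibble::tibble(woman_id = "w1",
#'                       onset = as.Date("2000-01-01") + c(0, 29, 58))
#' cycle_intervals(rec)
#' @export
cycle_intervals <- function(records, gap_days = .DEFAULT_GAP_DAYS) {
  records <- dplyr::arrange(records, .data$woman_id, .data$onset)
  purrr::map_dfr(split(records, records$woman_id), function(d) {
    if (nrow(d) < 2) {
      stop("need at least 2 onsets per woman (woman ", d$woman_id[1], ")",
           call. = FALSE)
    }
    len <- as.integer(diff(d$onset))
    tibble::tibble(
      woman_id = d$woman_id[1],
      start = d$onset[-nrow(d)],
      end = d$onset[-1],
      length = len,
      gap = len > gap_days
    )
  })
}

#' Split records into gap-free blocks
#'
#' Breaks each woman's onset series at gap-flagged intervals (see
#' [cycle_intervals()]) so that downstream period estimation and run
#' detection only ever see contiguous stretches of genuine cycles. The
#' total number of onsets is conserved; annotations travel with their
#' onsets.
#'
#' @inheritParams cycle_intervals
#' @return The input records with an added `block` column (integer id,
#'   consecutive within woman).
#' @export
split_on_gaps <- function(records, gap_days = .DEFAULT_GAP_DAYS) {
  per_woman <- function(d) {
    d <- dplyr::arrange(d, .data$onset)
    if (nrow(d) == 1) {
      d$block <- 1L
      return(d)
    }
    gaps <- as.integer(diff(d$onset)) > gap_days
    d$block <- cumsum(c(TRUE, gaps))
    d
  }
  grouped <- dplyr::group_by(records, .data$woman_id)
  out <- dplyr::ungroup(dplyr::group_modify(grouped, ~ per_woman(.x)))
  # group_modify drops/reorders the grouping column position; restore order
  dplyr::relocate(out, "woman_id")
}

#' Subset onsets by era, calendar months, or standstill window
#'
#' Implements the study-style subsets of pooled onsets: the pre/post-2010
#' era split (boundary 2010-01-01, onset-date based), calendar-month
#' filters (winter = December + January, summer = June + July), and
#' 3-year windows centred on a standstill epoch year (centre year plus or
#' minus one calendar year; centre 2025 uses 2023--2024 since that epoch
#' falls at the edge of the data era).
#'
#' @param records A records tibble.
#' @param mode One of `"all"`, `"era"`, `"months"`, `"standstill_window"`.
#' @param era For `mode = "era"`: `"pre2010"` or `"post2010"`.
#' @param months For `mode = "months"`: integer vector within 1..12.
#' @param center_year For `mode = "standstill_window"`: epoch year.
#' @return The filtered records tibble (order preserved).
#' @examples
#' rec <- tibble::tibble(woman_id = "w1",
#'                       onset = as.Date(c("2009-12-31", "2010-01-01")))
#' subset_onsets(rec, "era", era = "pre2010")
#' @export
subset_onsets <- function(records, mode = c("all", "era", "months",
                                            "standstill_window"),
                          era = c("pre2010", "post2010"),
                          months = NULL, center_year = NULL) {
  mode <- match.arg(mode)
  if (mode == "all") return(records)
  if (mode == "era") {
    era <- match.arg(era)
    boundary <- as.Date("2010-01-01")
    keep <- if (era == "pre2010") records$onset < boundary
            else records$onset >= boundary
    return(records[keep, , drop = FALSE])
  }
  if (mode == "months") {
    stopifnot(is.numeric(months), all(months %in% 1:12))
    keep <- as.integer(format(records$onset, "%m")) %in% months
    return(records[keep, , drop = FALSE])
  }
  stopifnot(is.numeric(center_year), length(center_year) == 1)
  years <- if (center_year == 2025) 2023:2024
           else (center_year - 1):(center_year + 1)
  keep <- as.integer(format(records$onset, "%Y")) %in% years
  records[keep, , drop = FALSE]
}
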