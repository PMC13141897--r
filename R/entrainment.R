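# Entrainment analysis: segmentation, period estimation, locked runs --------

.MIN_SEGMENT <- 6     # minimum intervals per segment
.CONSISTENT_SD <- 3   # max SD (days) of interval length for "consistent"
.RUN_TOLERANCE <- 0.1 # max deviation from the run mean, in cycles
.MIN_RUN <- 4         # minimum consecutive onsets in an entrained run

# Penalised binary segmentation of a numeric series into piecewise-constant
# means. Penalty beta * sigma2 * log(n) per changepoint.
#' @noRd
binseg_changepoints <- function(x, beta = 3, min_seg = .MIN_SEGMENT) {
  n <- length(x)
  if (n < 2 * min_seg) return(integer())
  sigma2 <- stats::var(diff(x)) / 2   # robust-ish noise estimate
  if (!is.finite(sigma2) || sigma2 < 1e-8) sigma2 <- 1e-8
  penalty <- beta * sigma2 * log(n)
  sse <- function(v) sum((v - mean(v))^2)
  best_split <- function(lo, hi) {
    # returns c(gain, k): split after index k (absolute), or NULL
    len <- hi - lo + 1
    if (len < 2 * min_seg) return(NULL)
    v <- x[lo:hi]
    total <- sse(v)
    ks <- min_seg:(len - min_seg)
    cs <- cumsum(v); css <- cumsum(v^2)
    left_sse <- css[ks] - cs[ks]^2 / ks
    right_n <- len - ks
    right_sum <- cs[len] - cs[ks]
    right_sse <- (css[len] - css[ks]) - right_sum^2 / right_n
    gains <- total - (left_sse + right_sse)
    k <- ks[which.max(gains)]
    c(max(gains), lo + k - 1)
  }
  cps <- integer()
  queue <- list(c(1, n))
  while (length(queue)) {
    seg <- queue[[1]]; queue <- queue[-1]
    sp <- best_split(seg[1], seg[2])
    if (!is.null(sp) && sp[1] > penalty) {
      k <- sp[2]
      cps <- c(cps, k)
      queue <- c(queue, list(c(seg[1], k)), list(c(k + 1, seg[2])))
    }
  }
  sort(cps)
}

#' Segment interval series into consistent-period episodes
#'
#' Automates the visual phase-jump calls of classical mensogram reading:
#' a penalised binary segmentation fits a piecewise-constant mean to the
#' interval-length series, splitting wherever the cycle length shifts.
#' Segments are at least `min_seg` intervals long; a segment is
#' `consistent` when the SD of its interval lengths is at most
#' `consistent_sd` days and its mean lies in 20--40 days.
#'
#' @param lengths Integer/numeric vector of successive interval lengths
#'   (days) from one gap-free block.
#' @param beta Penalty multiplier for the changepoint criterion
#'   (`beta * sigma^2 * log(n)`, default 3).
#' @param min_seg Minimum segment length in intervals (default 6).
#' @param consistent_sd Consistency threshold on the interval SD, days
#'   (default 3).
#' @return A tibble with one row per segment: `start`, `end` (interval
#'   indices), `n_intervals`, `mean_length`, `sd_length`, `consistent`.
#' @examples
#' segment_intervals(c(rep(29, 20), rep(25, 20)))
#' @export
segment_intervals <- function(lengths, beta = 3, min_seg = .MIN_SEGMENT,
                              consistent_sd = .CONSISTENT_SD) {
  n <- length(lengths)
  if (n < min_seg) {
    return(tibble::tibble(start = 1L, end = n, n_intervals = n,
                          mean_length = mean(lengths),
                          sd_length = stats::sd(lengths),
                          consistent = FALSE))
  }
  cps <- binseg_changepoints(lengths, beta = beta, min_seg = min_seg)
  bounds <- c(0L, cps, n)
  purrr::map_dfr(seq_len(length(bounds) - 1), function(i) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1]
    v <- lengths[lo:hi]
    sdv <- if (length(v) > 1) stats::sd(v) else Inf
    tibble::tibble(
      start = lo, end = hi, n_intervals = hi - lo + 1L,
      mean_length = mean(v), sd_length = sdv,
      consistent = length(v) >= min_seg && sdv <= consistent_sd &&
        mean(v) >= 20 && mean(v) <= 40
    )
  })
}

#' Free-running period by event-time periodogram
#'
#' Estimates the dominant period of an onset series on 20--40 days from
#' the periodogram of the onset times themselves: at each trial period P
#' the power is the Rayleigh power n * S(P)^2, where S(P) is the mean
#' resultant length of the onset phases 2 * pi * t_k / P. For an event
#' series of unit impulses this is the Schuster form of the
#' Lomb--Scargle periodogram with the spectral-window cross-term dropped;
#' keeping that cross-term (i.e. running the periodogram on the
#' binarized daily series) biases the peak upward by order P/n days,
#' while the event-time form peaks exactly at the true period for a
#' noise-free periodic train. Like the binarized form, it tolerates
#' occasional missed onsets inside a segment, which simple interval
#' means do not.
#'
#' @param onsets Date vector, or numeric onset times in days (>= 6
#'   onsets).
#' @param period_range Numeric length-2, scan range in days (default
#'   `c(20, 40)`).
#' @param period_step Grid resolution in days (default 0.01).
#' @return A list with `tau` (argmax period, days), `power` (peak
#'   Rayleigh power) and `periodogram` (tibble `period`, `power`). A
#'   peak on the grid boundary triggers a warning.
#' @examples
#' estimate_period(as.Date("2000-01-01") + round(seq(0, 19) * 29.5))
#' @export
estimate_period <- function(onsets, period_range = c(20, 40),
                            period_step = 0.01) {
  if (length(onsets) < 6) {
    stop("period estimation needs at least 6 onsets", call. = FALSE)
  }
  days <- as.numeric(onsets - min(onsets))
  n <- length(days)
  periods <- seq(period_range[1], period_range[2], by = period_step)
  wt <- outer(2 * pi / periods, days)   # n_freq x n_onsets
  C <- cos(wt) %*% rep(1, n)
  S <- sin(wt) %*% rep(1, n)
  power <- as.numeric(C^2 + S^2) / n    # Rayleigh power n * S(P)^2
  i <- which.max(power)
  if (i == 1 || i == length(periods)) {
    warning("periodogram peak on grid boundary", call. = FALSE)
  }
  list(tau = periods[i], power = power[i],
       periodogram = tibble::tibble(period = periods, power = power))
}

#' Detect entrained runs against one lunar cycle
#'
#' Finds maximal stretches of at least `min_run` consecutive onsets whose
#' phases within the chosen lunar cycle stay within `tolerance` cycles of
#' the stretch's own circular mean - i.e. a stable phase relation to the
#' reference event, wherever that phase sits (a run locked 2 days before
#' full moon counts as entrained). Reference and anti events are tested
#' separately; runs covering the same onsets from both framings are
#' deduplicated keeping the smaller circular variance.
#'
#' @param records One woman's records tibble (a single `woman_id`).
#' @param events A `lunar_events` tibble covering the onsets.
#' @param cycle `"synodic"`, `"anomalistic"` or `"tropical"`.
#' @param tolerance Max deviation from the run circular mean, in cycles
#'   (default 0.1, i.e. 36 degrees or about 3 days of the synodic month).
#' @param min_run Minimum run length in onsets (default 4).
#' @param gap_days Gap threshold separating contiguous blocks (default 60).
#' @return A tibble with one row per run: `woman_id`, `cycle`,
#'   `locked_kind`, `start_index`, `end_index` (onset indices within the
#'   woman's ordered record), `length`, `mean_phase` (radians),
#'   `mean_offset_days`, `circ_var`.
#' @export
detect_runs <- function(records, events, cycle = "synodic",
                        tolerance = .RUN_TOLERANCE, min_run = .MIN_RUN,
                        gap_days = .DEFAULT_GAP_DAYS) {
  stopifnot(length(unique(records$woman_id)) == 1)
  records <- dplyr::arrange(records, .data$onset)
  records$.idx <- seq_len(nrow(records))
  blocks <- split_on_gaps(records, gap_days = gap_days)
  info <- cycle_info(cycle)
  tol_rad <- tolerance * 2 * pi

  runs_for <- function(theta, idx, kind) {
    n <- length(theta)
    if (n < min_run) return(NULL)
    out <- list()
    s <- 1
    while (s <= n - min_run + 1) {
      e <- s + min_run - 1
      if (run_ok(theta[s:e], tol_rad)) {
        while (e < n && run_ok(theta[s:(e + 1)], tol_rad)) e <- e + 1
        m <- circular_mean_R(theta[s:e])
        offset_days <- ((m$mean_direction + pi) %% (2 * pi) - pi) /
          (2 * pi) * info$nominal_period
        out <- c(out, list(tibble::tibble(
          woman_id = records$woman_id[1], cycle = info$cycle,
          locked_kind = kind,
          start_index = idx[s], end_index = idx[e], length = e - s + 1L,
          mean_phase = m$mean_direction, mean_offset_days = offset_days,
          circ_var = 1 - m$S
        )))
        s <- e + 1
      } else {
        s <- s + 1
      }
    }
    if (length(out)) dplyr::bind_rows(out) else NULL
  }

  res <- list()
  for (b in unique(blocks$block[blocks$woman_id == records$woman_id[1]])) {
    blk <- blocks[blocks$block == b, ]
    if (nrow(blk) < min_run) next
    for (ref in c("reference", "anti")) {
      kind <- if (ref == "reference") info$reference_kind else info$anti_kind
      ph <- onset_phases(blk, events, cycle = cycle, reference = ref)
      res <- c(res, list(runs_for(ph$theta, blk$.idx, kind)))
    }
  }
  res <- dplyr::bind_rows(res)
  if (!nrow(res)) {
    return(tibble::tibble(woman_id = character(), cycle = character(),
                          locked_kind = character(), start_index = integer(),
                          end_index = integer(), length = integer(),
                          mean_phase = numeric(), mean_offset_days = numeric(),
                          circ_var = numeric()))
  }
  dedupe_runs(res)
}

# All deviations from the circular mean within tol (radians)?
#' @noRd
run_ok <- function(theta, tol_rad) {
  mu <- circular_mean_R(theta)$mean_direction
  dev <- abs(((theta - mu + pi) %% (2 * pi)) - pi)
  all(dev <= tol_rad)
}

# A reference-locked stretch shows up almost identically in the anti-event
# framing (the two kinds interleave regularly), so runs whose index ranges
# substantially coincide are duplicates: keep the tighter (smaller circular
# variance) one. Runs that merely brush each other are both real and kept.
#' @noRd
dedupe_runs <- function(runs) {
  runs <- dplyr::arrange(runs, .data$circ_var)
  keep <- rep(TRUE, nrow(runs))
  for (i in seq_len(nrow(runs))) {
    if (!keep[i] || i == nrow(runs)) next
    for (j in (i + 1):nrow(runs)) {
      if (!keep[j]) next
      inter <- min(runs$end_index[i], runs$end_index[j]) -
        max(runs$start_index[i], runs$start_index[j]) + 1
      longer <- max(runs$length[i], runs$length[j])
      if (inter >= 0.5 * longer) keep[j] <- FALSE
    }
  }
  dplyr::arrange(runs[keep, ], .data$start_index)
}

#' Limits-of-entrainment curve
#'
#' For every consistent free-running episode of every woman, determines
#' whether an entrained run of the given lunar cycle adjoins it (index
#' ranges overlapping or separated by at most one onset - the synchrony
#' may precede or follow the consistent free-run), then reports the
#' percentage of positive episodes per 1-day bin of the episode's
#' free-running period. Bins with no episodes carry no value.
#'
#' @param records A records tibble (any number of women).
#' @param events A `lunar_events` tibble covering the onsets.
#' @param cycles Character vector of cycles to scan (default all three).
#' @param tau_breaks Bin edges in days (default `seq(20, 40)`).
#' @param ... Passed to [detect_runs()] (`tolerance`, `min_run`) and
#'   segmentation (`gap_days`).
#' @param gap_days Gap threshold in days.
#' @return An `entrainment_curve` tibble: `cycle`, `bin_low`, `bin_high`,
#'   `n_episodes`, `n_entrained`, `percent_entrained`.
#' @export
entrainment_limits <- function(records, events, cycles = lunar_cycles()$cycle,
                               tau_breaks = seq(20, 40),
                               gap_days = .DEFAULT_GAP_DAYS, ...) {
  episodes <- consistent_episodes(records, gap_days = gap_days)
  if (!nrow(episodes)) {
    stop("no consistent free-running episodes found", call. = FALSE)
  }
  out <- purrr::map_dfr(cycles, function(cy) {
    runs <- purrr::map_dfr(unique(records$woman_id), function(w) {
      detect_runs(records[records$woman_id == w, ], events, cycle = cy,
                  gap_days = gap_days, ...)
    })
    ep <- episodes
    ep$entrained <- purrr::map_lgl(seq_len(nrow(ep)), function(i) {
      r <- runs[runs$woman_id == ep$woman_id[i], ]
      any(r$start_index <= ep$end_index[i] + 1 &
            r$end_index >= ep$start_index[i] - 1)
    })
    ep$bin <- cut(ep$tau, tau_breaks, right = FALSE, labels = FALSE)
    ep <- ep[!is.na(ep$bin), ]
    agg <- dplyr::summarise(
      dplyr::group_by(ep, .data$bin),
      n_episodes = dplyr::n(),
      n_entrained = sum(.data$entrained),
      .groups = "drop"
    )
    tibble::tibble(
      cycle = cy,
      bin_low = tau_breaks[agg$bin],
      bin_high = tau_breaks[agg$bin + 1],
      n_episodes = agg$n_episodes,
      n_entrained = agg$n_entrained,
      percent_entrained = 100 * agg$n_entrained / agg$n_episodes
    )
  })
  class(out) <- c("entrainment_curve", class(out))
  out
}

# One row per consistent segment of every woman's gap-free blocks, with
# onset index range and Lomb-Scargle tau.
#' @noRd
consistent_episodes <- function(records, gap_days = .DEFAULT_GAP_DAYS,
                                beta = 3) {
  blocks <- split_on_gaps(records, gap_days = gap_days)
  blocks <- dplyr::group_by(blocks, .data$woman_id)
  blocks <- dplyr::mutate(blocks, .idx = dplyr::row_number())
  blocks <- dplyr::ungroup(blocks)
  purrr::map_dfr(split(blocks, paste(blocks$woman_id, blocks$block)),
                 function(blk) {
    if (nrow(blk) < .MIN_SEGMENT + 1) return(NULL)
    blk <- dplyr::arrange(blk, .data$onset)
    lens <- as.numeric(diff(blk$onset))
    segs <- segment_intervals(lens, beta = beta)
    segs <- segs[segs$consistent & segs$n_intervals >= 6, ]
    if (!nrow(segs)) return(NULL)
    purrr::map_dfr(seq_len(nrow(segs)), function(i) {
      on_lo <- segs$start[i]; on_hi <- segs$end[i] + 1L
      tau <- tryCatch(
        estimate_period(blk$onset[on_lo:on_hi])$tau,
        warning = function(w) suppressWarnings(
          estimate_period(blk$onset[on_lo:on_hi])$tau),
        error = function(e) NA_real_
      )
      tibble::tibble(
        woman_id = blk$woman_id[1],
        start_index = blk$.idx[on_lo], end_index = blk$.idx[on_hi],
        n_intervals = segs$n_intervals[i],
        mean_length = segs$mean_length[i],
        tau = tau
      )
    })
  })
}
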