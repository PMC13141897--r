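# Circular phase statistics: lunar phases, Rayleigh and V tests -------------

#' Phase of each onset within a lunar cycle
#'
#' Maps every onset to its phase in the chosen lunar cycle: an onset at
#' time t (anchored at 00:00 UTC of the onset day) falling between
#' consecutive reference events at t_prev and t_next gets
#' theta = 2 * pi * (t - t_prev) / (t_next - t_prev), i.e. the position is
#' normalised to the exact length of the bracketing interval rather than
#' to the nominal month length. An onset exactly at a reference event gets
#' theta = 0.
#'
#' @param records A records tibble (`woman_id`, `onset`).
#' @param events A `lunar_events` tibble covering all onsets.
#' @param cycle `"synodic"`, `"anomalistic"` or `"tropical"`.
#' @param reference `"reference"` (full moon / perigee / northern
#'   standstill) or `"anti"` (new moon / apogee / southern standstill).
#' @return A `phase_samples` tibble: `woman_id`, `onset`, `cycle`,
#'   `theta` (radians in `[0, 2*pi)`), `prev_event`, `next_event`.
#' @export
onset_phases <- function(records, events, cycle = "synodic",
                         reference = c("reference", "anti")) {
  reference <- match.arg(reference)
  info <- cycle_info(cycle)
  kind <- if (reference == "reference") info$reference_kind else info$anti_kind
  ref_times <- sort(events$time[events$kind == kind])
  if (length(ref_times) < 2) {
    stop("event series has fewer than 2 events of kind ", kind,
         call. = FALSE)
  }
  t_onset <- as.POSIXct(as.character(records$onset), tz = "UTC")
  if (any(t_onset < ref_times[1] | t_onset >= ref_times[length(ref_times)])) {
    stop("onsets outside event-series coverage", call. = FALSE)
  }
  i <- findInterval(as.numeric(t_onset), as.numeric(ref_times))
  prev <- ref_times[i]
  nxt <- ref_times[i + 1]
  theta <- 2 * pi * as.numeric(t_onset - prev, units = "days") /
    as.numeric(nxt - prev, units = "days")
  out <- tibble::tibble(
    woman_id = records$woman_id,
    onset = records$onset,
    cycle = info$cycle,
    theta = theta %% (2 * pi),
    prev_event = prev,
    next_event = nxt
  )
  class(out) <- c("phase_samples", class(out))
  out
}

#' Axial phase duplication
#'
#' Doubles angles modulo 2*pi, folding an axial bimodal distribution with
#' modes at mu and mu + pi (e.g. onsets locked either to the full or to
#' the new moon) into a unimodal one before directional testing.
#'
#' @param theta Numeric vector of phases in radians.
#' @return `(2 * theta) mod 2*pi`.
#' @examples
#' double_phase(c(0, pi / 2, pi, 3 * pi / 2))
#' @export
double_phase <- function(theta) {
  (2 * theta) %% (2 * pi)
}

#' Circular mean direction and mean resultant length
#'
#' @param theta Numeric vector of phases in radians.
#' @return A list with `mean_direction` (radians in `[0, 2*pi)`) and `S`
#'   (mean resultant length in `[0, 1]`).
#' @examples
#' circular_mean_R(c(0, pi / 2))
#' @export
circular_mean_R <- function(theta) {
  if (!length(theta)) stop("empty phase vector", call. = FALSE)
  C <- mean(cos(theta)); S <- mean(sin(theta))
  list(mean_direction = atan2(S, C) %% (2 * pi), S = sqrt(C^2 + S^2))
}

#' Rayleigh test for non-uniformity of circular data
#'
#' Tests the pooled phases against the uniform null using the Rayleigh
#' statistic Z = n * S^2 with the standard small-sample exponential
#' correction for the p-value.
#'
#' @param theta Numeric vector of phases in radians (n >= 4).
#' @param doubled Were the phases axially duplicated before testing?
#'   Carried through to the result for reporting.
#' @return A `rayleigh_test` object: list with `n`, `S`, `mean_direction`,
#'   `statistic` (Z), `p`, `variant = "uniform"`, `doubled`.
#' @examples
#' rayleigh_test(rep(1, 10))
#' @export
rayleigh_test <- function(theta, doubled = FALSE) {
  n <- length(theta)
  if (n < 4) stop("Rayleigh test needs n >= 4", call. = FALSE)
  m <- circular_mean_R(theta)
  R <- n * m$S
  Z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  structure(
    list(n = n, S = m$S, mean_direction = m$mean_direction,
         statistic = Z, p = min(max(p, .Machine$double.xmin), 1),
         variant = "uniform", doubled = doubled, mu0 = NA_real_),
    class = "rayleigh_test"
  )
}

#' Directed (V) test for concentration around a specified direction
#'
#' Modified Rayleigh test against the alternative of a unimodal
#' concentration at a known direction `mu0` (phase 0 = the reference
#' lunar event, after duplication also its anti-event). The statistic is
#' V = S * cos(mean - mu0), with u = V * sqrt(2 n) referred to the upper
#' tail of the standard normal.
#'
#' @inheritParams rayleigh_test
#' @param mu0 Hypothesised mean direction in radians (default 0).
#' @return A `rayleigh_test` object with `variant = "directed"`.
#' @examples
#' v_test(rep(0, 20))
#' @export
v_test <- function(theta, mu0 = 0, doubled = FALSE) {
  n <- length(theta)
  if (n < 4) stop("V test needs n >= 4", call. = FALSE)
  m <- circular_mean_R(theta)
  V <- m$S * cos(m$mean_direction - mu0)
  u <- V * sqrt(2 * n)
  p <- stats::pnorm(u, lower.tail = FALSE)
  structure(
    list(n = n, S = m$S, mean_direction = m$mean_direction,
         statistic = u, p = min(max(p, .Machine$double.xmin), 1),
         variant = "directed", doubled = doubled, mu0 = mu0),
    class = "rayleigh_test"
  )
}

#' @export
print.rayleigh_test <- function(x, ...) {
  lab <- if (x$variant == "uniform") "Rayleigh test (uniform null)"
         else sprintf("V test (directed, mu0 = %.3f)", x$mu0)
  cat(lab, if (x$doubled) "[phases doubled]" else "", "\n")
  cat(sprintf("  n = %d, S = %.4f, mean direction = %.4f rad\n",
              x$n, x$S, x$mean_direction))
  cat(sprintf("  statistic = %.4f, p = %.4g\n", x$statistic, x$p))
  invisible(x)
}

#' 30-bin circular histogram of phases
#'
#' @param theta Numeric vector of phases in radians.
#' @param cycle Cycle label carried in the result.
#' @param doubled Were the phases axially duplicated?
#' @param nbins Number of equal-width bins (default 30, roughly one day
#'   per bin for the synodic month).
#' @return A `circular_histogram` tibble: `bin`, `bin_start`, `bin_mid`,
#'   `count`, with attributes `cycle`, `doubled`, `n`.
#' @export
phase_histogram <- function(theta, cycle = "synodic", doubled = FALSE,
                            nbins = 30) {
  if (!length(theta)) stop("empty phase vector", call. = FALSE)
  width <- 2 * pi / nbins
  bin <- pmin(floor((theta %% (2 * pi)) / width), nbins - 1) + 1
  counts <- tabulate(bin, nbins)
  out <- tibble::tibble(
    bin = seq_len(nbins),
    bin_start = (seq_len(nbins) - 1) * width,
    bin_mid = (seq_len(nbins) - 0.5) * width,
    count = counts
  )
  attr(out, "cycle") <- cycle
  attr(out, "doubled") <- doubled
  attr(out, "n") <- length(theta)
  class(out) <- c("circular_histogram", class(out))
  out
}

# Pooled-phase S value at or above which a distribution is reported as
# highly peaked.
.PEAKED_S <- 0.10

#' Pooled circular phase analysis of a cohort
#'
#' The population-level analysis: onsets (optionally subset by era,
#' season or standstill window) are mapped to phases of one lunar cycle,
#' optionally axially duplicated, then tested with both the uniform-null
#' Rayleigh test and the directed V test (mu0 = 0, the reference event),
#' and binned into a 30-sector circular histogram. Distributions with
#' mean resultant length S >= 0.10 are flagged as highly peaked.
#'
#' @param records A records tibble.
#' @param events A `lunar_events` tibble covering the onsets.
#' @param cycle `"synodic"`, `"anomalistic"` or `"tropical"`.
#' @param doubled Apply axial phase duplication before testing
#'   (default `TRUE`, appropriate when onsets may lock to either the
#'   reference or the anti event).
#' @param mu0 Direction for the V test, radians (default 0).
#' @param ... Passed to [subset_onsets()] (e.g. `mode`, `era`, `months`).
#' @return A `pooled_phase_analysis` object: list with `cycle`, `subset`,
#'   `n`, `doubled`, `histogram`, `rayleigh`, `v_test`, `S`, `peaked`.
#' @export
pooled_phase_analysis <- function(records, events, cycle = "synodic",
                                  doubled = TRUE, mu0 = 0, ...) {
  sub <- subset_onsets(records, ...)
  if (!nrow(sub)) stop("no onsets left after subsetting", call. = FALSE)
  ph <- onset_phases(sub, events, cycle = cycle)
  theta <- if (doubled) double_phase(ph$theta) else ph$theta
  ray <- rayleigh_test(theta, doubled = doubled)
  vt <- v_test(theta, mu0 = mu0, doubled = doubled)
  hist <- phase_histogram(theta, cycle = cycle, doubled = doubled)
  subset_label <- paste(vapply(list(...), function(x)
    paste(as.character(x), collapse = "+"), character(1)), collapse = ":")
  if (!nzchar(subset_label)) subset_label <- "all"
  structure(
    list(cycle = cycle, subset = subset_label, n = ray$n, doubled = doubled,
         histogram = hist, rayleigh = ray, v_test = vt,
         S = ray$S, peaked = ray$S >= .PEAKED_S),
    class = "pooled_phase_analysis"
  )
}

#' @export
print.pooled_phase_analysis <- function(x, ...) {
  cat(sprintf("Pooled phase analysis: %s cycle, subset = %s%s\n",
              x$cycle, x$subset, if (x$doubled) " (phases doubled)" else ""))
  cat(sprintf("  n = %d, S = %.4f%s\n", x$n, x$S,
              if (x$peaked) " (highly peaked)" else ""))
  cat(sprintf("  Rayleigh p = %.4g, V-test p = %.4g\n",
              x$rayleigh$p, x$v_test$p))
  invisible(x)
}

#' Draw from a von Mises distribution
#'
#' Best--Fisher acceptance/rejection sampler; used by the synthetic-cohort
#' tests and available for power experiments.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (>= 0; 0 gives the uniform circle).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}
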