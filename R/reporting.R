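# Mensograms, polar plots, pipeline ------------------------------------------

#' Fold a record and event series for mensogram plotting
#'
#' Computes the raster coordinates of an actogram-style mensogram: time
#' from the first onset is cut into consecutive windows of `fold_period`
#' days (one raster row each), and every onset/event is placed at its
#' day-within-window, horizontally repeated `n_repeats` times so courses
#' crossing the fold remain readable.
#'
#' @param record One woman's records tibble.
#' @param events Optional `lunar_events` tibble for overlay lines.
#' @param fold_period Fold period in days (default 29.53, the synodic
#'   month); must lie in 20--40.
#' @param n_repeats Horizontal repeats (default 3).
#' @param overlays Event kinds to fold as overlay lines.
#' @return A list of tibbles `onsets` (`row`, `x`, `repeat_index`, `tag`)
#'   and `events` (`row`, `x`, `repeat_index`, `kind`), plus the spec.
#' @export
mensogram_data <- function(record, events = NULL, fold_period = 29.53,
                           n_repeats = 3,
                           overlays = c("full_moon", "new_moon")) {
  stopifnot(fold_period >= 20, fold_period <= 40, n_repeats >= 1,
            nrow(record) > 0)
  origin <- min(record$onset)
  fold <- function(days) {
    row <- floor(days / fold_period)
    x <- days - row * fold_period
    purrr::map_dfr(seq_len(n_repeats) - 1, function(r) {
      tibble::tibble(row = row, x = x + r * fold_period, repeat_index = r + 1)
    })
  }
  on_days <- as.numeric(record$onset - origin)
  onsets <- fold(on_days)
  onsets$tag <- rep(if ("tag" %in% names(record)) record$tag
                    else NA_character_, n_repeats)
  ev <- NULL
  if (!is.null(events) && length(overlays)) {
    sub <- events[events$kind %in% overlays, ]
    span_end <- max(record$onset) + 1
    keep <- as.Date(sub$time) >= origin & as.Date(sub$time) <= span_end
    sub <- sub[keep, ]
    if (nrow(sub)) {
      ev_days <- as.numeric(difftime(sub$time,
                                     as.POSIXct(as.character(origin),
                                                tz = "UTC"),
                                     units = "days"))
      ev <- fold(ev_days)
      ev$kind <- rep(sub$kind, n_repeats)
    }
  }
  list(onsets = onsets, events = ev,
       fold_period = fold_period, n_repeats = n_repeats,
       n_rows = max(onsets$row) + 1, origin = origin)
}

# Overlay palette following the classic mensogram legend.
.EVENT_COLOURS <- c(full_moon = "#E6B800", new_moon = "#2255CC",
                    perigee = "#B07FD6", apogee = "#E67E22",
                    standstill_n = "#E75480", standstill_s = "#2E8B57")

#' Plot a mensogram
#'
#' Raster plot of one woman's menses onsets folded at a chosen period
#' (rows = consecutive fold windows, top to bottom), repeated
#' horizontally, with lunar events of the requested kinds drawn as
#' coloured lines across rows and births/miscarriages marked.
#'
#' @inheritParams mensogram_data
#' @return A ggplot object.
#' @export
plot_mensogram <- function(record, events = NULL, fold_period = 29.53,
                           n_repeats = 3,
                           overlays = c("full_moon", "new_moon")) {
  md <- mensogram_data(record, events, fold_period, n_repeats, overlays)
  p <- ggplot2::ggplot()
  if (!is.null(md$events)) {
    p <- p + ggplot2::geom_path(
      data = dplyr::arrange(md$events, .data$kind, .data$repeat_index,
                            .data$row),
      ggplot2::aes(x = .data$x, y = .data$row, colour = .data$kind,
                   group = interaction(.data$kind, .data$repeat_index)),
      linewidth = 0.4, alpha = 0.8
    ) +
      ggplot2::scale_colour_manual(values = .EVENT_COLOURS, name = "event")
  }
  p <- p + ggplot2::geom_point(
    data = md$onsets,
    ggplot2::aes(x = .data$x, y = .data$row), size = 0.7
  )
  ann <- md$onsets[!is.na(md$onsets$tag), ]
  if (nrow(ann)) {
    p <- p + ggplot2::geom_point(
      data = ann, ggplot2::aes(x = .data$x, y = .data$row),
      shape = 8, colour = "red", size = 2
    )
  }
  p +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = sprintf("days (folded at %.2f d, repeated %dx)",
                  md$fold_period, md$n_repeats),
      y = "fold window",
      title = unique(record$woman_id)[1]
    ) +
    ggplot2::theme_minimal()
}

#' Polar (rose) plot of a circular phase histogram
#'
#' 30-sector rose diagram of onset phases, annotated with the sample
#' size (lower left), test p-values (top left) and the mean resultant
#' length S (top right), following the conventional layout of circular
#' menses-phase figures. Phase 0 (the reference event) points up.
#'
#' @param histogram A `circular_histogram` tibble (see
#'   [phase_histogram()]).
#' @param rayleigh,v_test Optional `rayleigh_test` objects used for the
#'   annotations.
#' @return A ggplot object.
#' @export
plot_polar <- function(histogram, rayleigh = NULL, v_test = NULL) {
  n <- attr(histogram, "n")
  lab_tl <- paste(c(
    if (!is.null(v_test)) sprintf("p[dir] = %.3g", v_test$p),
    if (!is.null(rayleigh)) sprintf("p[unif] = %.3g", rayleigh$p)
  ), collapse = "\n")
  lab_tr <- if (!is.null(rayleigh)) sprintf("S = %.3f", rayleigh$S) else ""
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 2 * pi / nrow(histogram), fill = "grey35",
                      colour = "white", linewidth = 0.2) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(
      limits = c(0, 2 * pi),
      breaks = seq(0, 3 * pi / 2, by = pi / 2),
      labels = c("0", "π/2", "π", "3π/2")
    ) +
    ggplot2::labs(
      title = sprintf("%s cycle%s", attr(histogram, "cycle"),
                      if (isTRUE(attr(histogram, "doubled")))
                        " (phases doubled)" else ""),
      subtitle = lab_tl,
      caption = sprintf("n = %d          %s", n, lab_tr),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.circular_histogram <- function(object, ...) plot_polar(object, ...)

#' @export
autoplot.pooled_phase_analysis <- function(object, ...) {
  plot_polar(object$histogram, rayleigh = object$rayleigh,
             v_test = object$v_test)
}

#' @export
autoplot.entrainment_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$percent_entrained,
                               colour = .data$cycle)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_episodes)) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "free-running period (days)",
                  y = "% episodes entrained",
                  colour = "lunar cycle", size = "episodes") +
    ggplot2::theme_minimal()
}

#' Run the full analysis pipeline
#'
#' End-to-end deterministic pipeline over a cohort of records: computes
#' (or loads) the lunar event series, detects per-woman segments and
#' entrained runs, builds the limits-of-entrainment curves, and performs
#' pooled circular phase analyses for the standard subsets (all,
#' pre/post-2010, winter, summer, standstill windows) against all three
#' lunar cycles, writing every artifact into `out_dir`.
#'
#' @param records A records tibble.
#' @param events Optional `lunar_events` tibble; computed from the record
#'   span when `NULL` (a supplied file-based series takes precedence, so
#'   printed-almanac inputs can be reproduced bit-for-bit).
#' @param out_dir Output directory (created; partial outputs are removed
#'   if the pipeline fails).
#' @param subsets Named list of [subset_onsets()] argument lists.
#' @param cycles Cycles to analyse.
#' @param figures Also write PNG figures (default `FALSE`; numeric and
#'   tabular outputs are always written).
#' @param standstill_centers Epoch years for standstill-window subsets.
#' @return Invisibly, the parsed summary list (also serialised as
#'   versioned JSON `summary.json` with 6-significant-digit numbers).
#' @export
run_pipeline <- function(records, events = NULL, out_dir,
                         cycles = lunar_cycles()$cycle,
                         subsets = NULL,
                         standstill_centers = c(2015),
                         figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)

  if (is.null(events)) {
    span <- range(records$onset)
    events <- lunar_events(span[1] - 45, span[2] + 45)
  }
  write_event_csv(events, file.path(out_dir, "events.csv"))

  if (is.null(subsets)) {
    subsets <- list(
      all = list(mode = "all"),
      pre2010 = list(mode = "era", era = "pre2010"),
      post2010 = list(mode = "era", era = "post2010"),
      winter = list(mode = "months", months = c(12, 1)),
      summer = list(mode = "months", months = c(6, 7))
    )
    for (yy in standstill_centers) {
      subsets[[paste0("standstill", yy)]] <-
        list(mode = "standstill_window", center_year = yy)
    }
  }

  # per-woman runs and consistent episodes
  runs <- purrr::map_dfr(cycles, function(cy) {
    purrr::map_dfr(unique(records$woman_id), function(w) {
      detect_runs(records[records$woman_id == w, ], events, cycle = cy)
    })
  })
  utils::write.csv(runs, file.path(out_dir, "runs.csv"), row.names = FALSE)

  curve <- tryCatch(entrainment_limits(records, events, cycles = cycles),
                    error = function(e) NULL)
  if (!is.null(curve)) {
    utils::write.csv(
      data.frame(cycle = curve$cycle, bin_low_days = curve$bin_low,
                 bin_high_days = curve$bin_high,
                 n_episodes = curve$n_episodes,
                 percent_entrained = curve$percent_entrained),
      file.path(out_dir, "entrainment_curve.csv"), row.names = FALSE)
  }

  analyses <- list()
  for (sname in names(subsets)) {
    for (cy in cycles) {
      key <- paste(sname, cy, sep = ".")
      res <- tryCatch(
        do.call(pooled_phase_analysis,
                c(list(records = records, events = events, cycle = cy,
                       doubled = TRUE), subsets[[sname]])),
        error = function(e) NULL
      )
      if (is.null(res)) {
        message("subset ", sname, " x ", cy, ": no analysable onsets, skipped")
        next
      }
      analyses[[key]] <- list(
        cycle = cy, subset = sname, n = res$n, doubled = res$doubled,
        S = signif(res$S, 6), p_uniform = signif(res$rayleigh$p, 6),
        p_directed = signif(res$v_test$p, 6), peaked_flag = res$peaked
      )
      utils::write.csv(
        data.frame(bin_start_rad = res$histogram$bin_start,
                   count = res$histogram$count),
        file.path(out_dir, paste0("histogram_", key, ".csv")),
        row.names = FALSE)
      if (figures) {
        grDevices::png(file.path(out_dir, paste0("polar_", key, ".png")),
                       width = 700, height = 700, res = 120)
        print(autoplot.pooled_phase_analysis(
          structure(res, class = "pooled_phase_analysis")))
        grDevices::dev.off()
      }
    }
  }

  summary <- list(
    schema_version = "1.0",
    n_women = length(unique(records$woman_id)),
    n_onsets = nrow(records),
    n_runs = nrow(runs),
    analyses = analyses
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(summary)
}
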