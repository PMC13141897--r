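# broom-style tidiers ---------------------------------------------------------

#' Tidy a Rayleigh/V test result
#'
#' @param x A `rayleigh_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `variant`, `doubled`, `n`, `S`,
#'   `mean_direction`, `statistic`, `p.value`, `mu0`.
#' @export
tidy.rayleigh_test <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, doubled = x$doubled, n = x$n, S = x$S,
    mean_direction = x$mean_direction, statistic = x$statistic,
    p.value = x$p, mu0 = x$mu0
  )
}

#' Tidy a pooled phase analysis
#'
#' @param x A `pooled_phase_analysis` object.
#' @param ... Unused.
#' @return A two-row tibble (one per test) with the subset and cycle
#'   labels attached.
#' @export
tidy.pooled_phase_analysis <- function(x, ...) {
  dplyr::mutate(
    dplyr::bind_rows(tidy.rayleigh_test(x$rayleigh),
                     tidy.rayleigh_test(x$v_test)),
    cycle = x$cycle, subset = x$subset, .before = 1
  )
}

#' One-line summary of a pooled phase analysis
#'
#' @param x A `pooled_phase_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: `cycle`, `subset`, `n`, `doubled`, `S`,
#'   `p_uniform`, `p_directed`, `peaked`.
#' @export
glance.pooled_phase_analysis <- function(x, ...) {
  tibble::tibble(
    cycle = x$cycle, subset = x$subset, n = x$n, doubled = x$doubled,
    S = x$S, p_uniform = x$rayleigh$p, p_directed = x$v_test$p,
    peaked = x$peaked
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
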