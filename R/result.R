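# Broom-style accessors and plots for fitted completion objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-iteration trace of a completion fit
#'
#' @param x a `"ctnm_fit"` from [ctnm_qr()].
#' @param ... unused.
#' @return a tibble with one row per iteration: `iteration`,
#'   `rel_change`.
#' @method tidy ctnm_fit
#' @export
tidy.ctnm_fit <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$rel_change_trace),
    rel_change = x$rel_change_trace
  )
}

#' One-row summary of a completion fit
#'
#' @param x a `"ctnm_fit"` from [ctnm_qr()].
#' @param ... unused.
#' @return a one-row tibble: `iterations`, `stop_reason`,
#'   `final_rel_change`, `mu_final`, `rank`, `strategy`.
#' @method glance ctnm_fit
#' @export
glance.ctnm_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    stop_reason = x$stop_reason,
    final_rel_change = x$rel_change_trace[length(x$rel_change_trace)],
    mu_final = x$mu_final,
    rank = paste(x$config$rank, collapse = "x"),
    strategy = x$config$factor_strategy
  )
}

#' Convergence plot for a completion fit
#'
#' Plots the per-iteration relative change of the completed tensor on a
#' log scale.
#'
#' @param object a `"ctnm_fit"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ctnm_fit
#' @export
autoplot.ctnm_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$rel_change)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration",
                  y = "relative change of completed tensor",
                  title = "CTNM-QR convergence") +
    ggplot2::theme_minimal()
}

#' Benchmark plot: mean RSE against missing rate
#'
#' @param object a benchmark tibble from [run_benchmark()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ctnm_benchmark
#' @export
autoplot.ctnm_benchmark <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mr, y = .data$mean_rse,
                               colour = .data$shape, group = .data$shape)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "missing rate", y = "mean RSE",
                  colour = "tensor size") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
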