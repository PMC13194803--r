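#' Plot fitted survival models against the digitized points
#'
#' @param curves Long KM-curve tibble (columns `arm`, `endpoint`,
#'   `time_months`, `survival`).
#' @param fits A `trial_fits` object from [fit_trial_curves()].
#' @param horizon_months Extrapolation horizon to draw.
#' @return A ggplot.
#' @export
plot_survival_fits <- function(curves, fits, horizon_months = 60) {
  grid <- seq(0, horizon_months, by = 0.25)
  lines <- purrr::map_dfr(names(fits$models), function(arm) {
    purrr::map_dfr(names(fits$models[[arm]]), function(ep) {
      m <- fits$models[[arm]][[ep]]
      tibble::tibble(arm = arm, endpoint = ep, time_months = grid,
                     survival = surv_prob(m, grid), family = m$family)
    })
  })
  ggplot2::ggplot(lines,
                  ggplot2::aes(x = .data$time_months, y = .data$survival,
                               colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = curves, size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~endpoint) +
    ggplot2::labs(x = "Time (months)", y = "Survival proportion",
                  colour = "Arm") +
    ggplot2::theme_minimal()
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param tornado A [one_way_dsa()] table.
#' @return A ggplot.
#' @export
plot_tornado <- function(tornado) {
  base <- attr(tornado, "icur_base")
  d <- dplyr::mutate(tornado,
                     parameter = factor(.data$parameter,
                                        levels = rev(.data$parameter)))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icur_low,
                                       xend = .data$icur_high,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICUR (euro/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A [run_psa()] result.
#' @return A ggplot.
#' @export
plot_ceac <- function(psa) {
  ggplot2::ggplot(psa$ceac, ggplot2::aes(x = .data$wtp,
                                         y = .data$prob_ce)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (euro/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effect scatter of the PSA iterations
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay line to draw (euro/QALY); `NULL` for
#'   none.
#' @return A ggplot.
#' @export
plot_psa_scatter <- function(psa, wtp = NULL) {
  p <- ggplot2::ggplot(psa$draws,
                       ggplot2::aes(x = .data$delta_qaly,
                                    y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (euro)") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = 2)
  }
  p
}

#' @describeIn run_cohort State-occupancy trace plot.
#' @param object A `cohort_trace`.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[, c("cycle", "stable", "progressive", "dead")],
    cols = c("stable", "progressive", "dead"),
    names_to = "state", values_to = "occupancy")
  d$state <- factor(d$state, levels = c("stable", "progressive", "dead"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                  colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle", y = "Occupancy", colour = "State") +
    ggplot2::theme_minimal()
}
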