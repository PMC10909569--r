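# ggplot2 displays for the analysis results.

#' @describeIn fit_asl Measured points and fitted curve per contrast phase.
#' @param object A `ceasl_fit`.
#' @param ... Ignored.
#' @export
autoplot.ceasl_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$time, colour = .data$phase)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$dm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "time from labelling onset (s)",
                  y = expression(Delta * M), colour = "phase")
}

#' Plot T1-error propagation curves
#'
#' Relative error of each fitted parameter against the relative error in the
#' perturbed relaxation time, one panel per parameter.
#'
#' @param table Output of [propagate_t1_errors()] (rows from one or several
#'   targets may be bound together).
#' @return A ggplot.
#' @export
plot_error_propagation <- function(table) {
  long <- tidyr::pivot_longer(table, dplyr::starts_with("eps_"),
                              names_to = "parameter", names_prefix = "eps_",
                              values_to = "eps")
  ggplot2::ggplot(long, ggplot2::aes(100 * .data$perturbation, .data$eps,
                                     colour = .data$target)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-10, 10), linetype = 3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "T1 error (%)", y = "parameter error (%)",
                  colour = "perturbed T1")
}

#' Plot a Monte Carlo simulation report
#'
#' CoV of each parameter against the swept condition (ground-truth exchange
#' rate or ROI size).
#'
#' @param report Output of [run_mc_study()] (rows from several conditions
#'   may be bound together).
#' @param x Which column to place on the x axis: `"kb_truth"` or
#'   `"roi_size"`.
#' @return A ggplot.
#' @export
plot_mc_report <- function(report, x = c("kb_truth", "roi_size")) {
  x <- match.arg(x)
  long <- tidyr::pivot_longer(report, dplyr::starts_with("cov_"),
                              names_to = "parameter", names_prefix = "cov_",
                              values_to = "cov")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data[[x]], .data$cov,
                                          colour = .data$parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = x, y = "CoV (%)", colour = "parameter")
  if (x == "roi_size") p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot blood-T1 recovery after injection for several dose fractions
#'
#' @param vif A full-dose [vif_curve()].
#' @param fractions Dose fractions to display.
#' @param relax A [relaxivity_params()].
#' @param target_t1 Target blood T1 marked with a horizontal line, s.
#' @return A ggplot.
#' @export
plot_t1_recovery <- function(vif, fractions = c(0.25, 0.5, 0.75, 1),
                             relax = relaxivity_params(), target_t1 = 0.8) {
  curves <- purrr::map(fractions, function(fr) {
    v <- scale_dose(vif, fr)
    tibble(t = v$t, t1b = gbca_t1b_post(v$cb, relax), dose = factor(fr))
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(.data$t, .data$t1b,
                                       colour = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = target_t1, linetype = 3) +
    ggplot2::labs(x = "time post-injection (min)",
                  y = expression(T[1][",b"] ~ "(s)"), colour = "dose fraction")
}
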