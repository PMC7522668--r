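#' Plot a g2 curve
#'
#' @param object A [g2_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g2_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau_s, y = .data$g2)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(g[2](tau)))
}

#' Plot the population-study property distributions
#'
#' Requires the population to have been sampled with `keep_samples = TRUE`;
#' otherwise plots the per-wavelength means with SD error bars.
#'
#' @param object A `dcsim_population`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcsim_population <- function(object, ...) {
  long <- tidy(object)
  wide <- tidyr::pivot_wider(long, names_from = "statistic",
                             values_from = "value")
  ggplot2::ggplot(wide, ggplot2::aes(x = factor(.data$wavelength_nm),
                                     y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~.data$property, scales = "free_y") +
    ggplot2::labs(x = "wavelength (nm)", y = "population mean ± SD")
}

#' Plot detection probability versus deep-flow change
#'
#' @param object A `dcsim_power_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcsim_power_study <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$change_pct, y = .data$p_detect,
                               colour = factor(.data$wavelength_nm))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2) +
    ggplot2::labs(x = "deep blood-flow increase (%)",
                  y = "detection probability",
                  colour = "wavelength (nm)") +
    ggplot2::ylim(0, 1)
}

#' Plot a BFi fit
#'
#' @param object A `bfi_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bfi_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$tau_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g2, alpha = .data$in_window),
                        show.legend = FALSE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(g[2](tau)),
                  subtitle = sprintf("BFi = %.3e cm^2/s", object$bfi))
}
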