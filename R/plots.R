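# ggplot2 autoplot methods for result objects.

#' Plot a scattering curve
#'
#' @param object a `saxs_curve`.
#' @param log_y use a logarithmic intensity axis.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot saxs_curve
#' @export
autoplot.saxs_curve <- function(object, log_y = FALSE, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$value))
  if ("error" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$error,
                   ymax = .data$value + .data$error),
      alpha = 0.25
    )
  }
  p <- p + ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(q ~ (ring(A)^{-1})),
      y = switch(attr(object, "kind") %||% "curve",
                 form_factor = "F(q)", s_eff = expression(S[eff](q)),
                 "I(q)")
    ) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a titration net-charge trace
#'
#' @param object a `titration_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot titration_result
#' @export
autoplot.titration_result <- function(object, ...) {
  ggplot2::ggplot(object$net_charge_trace,
                  ggplot2::aes(x = .data$sweep, y = .data$net_charge)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$burn_in, linetype = "dashed") +
    ggplot2::labs(x = "MC sweep", y = "net charge (e)") +
    ggplot2::theme_minimal()
}

#' Plot a chi-squared table as a heat map
#'
#' Log-scaled fill mirroring the usual presentation of (Q_eff, eps) scans.
#'
#' @param object a `chi2_scan`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot chi2_scan
#' @export
autoplot.chi2_scan <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$eps), y = factor(.data$qeff),
                               fill = log10(.data$chi2))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ chi^2)) +
    ggplot2::labs(x = expression(epsilon[ij] ~ (k[B] * T)),
                  y = expression(Q[eff] ~ (e))) +
    ggplot2::theme_minimal()
}

#' Plot an MC energy trace
#'
#' @param object an `mc_trajectory`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mc_trajectory
#' @export
autoplot.mc_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$energies,
                  ggplot2::aes(x = .data$sample, y = .data$total)) +
    ggplot2::geom_line(colour = "darkred") +
    ggplot2::labs(x = "sample", y = expression(beta * U)) +
    ggplot2::theme_minimal()
}
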