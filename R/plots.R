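#' Plot an inhibition time course
#'
#' Residual activity against preincubation time, optionally on the
#' conventional semi-log scale on which first-order decays are straight
#' lines.
#'
#' @param object An `inhibition_time_course`.
#' @param semilog Plot `log10(activity)` on the y axis?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inhibition_time_course <- function(object, semilog = TRUE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_min,
                                    y = .data$activity_pct)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "Preincubation time (min)",
                  y = "Residual activity (%)",
                  title = sprintf("Reporter: %s", attr(object, "reporter"))) +
    ggplot2::theme_minimal()
  if (semilog) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

#' Plot a decay fit over its data
#'
#' @param object A `decay_fit`.
#' @param tc The `inhibition_time_course` the fit was performed on.
#' @param semilog Semi-log y axis?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, tc, semilog = TRUE, ...) {
  grid <- tibble(time_min = seq(min(tc$time_min), max(tc$time_min),
                                length.out = 200))
  est <- setNames(object$params$estimate, object$params$term)
  grid$activity_pct <- if (identical(object$model, "mono")) {
    est["E0_pct"] * exp(-est["kapp"] * grid$time_min)
  } else {
    est["Y_pct"] * exp(-est["kapp1"] * grid$time_min) +
      (est["E0_pct"] - est["Y_pct"]) * exp(-est["kapp2"] * grid$time_min)
  }
  p <- ggplot2::ggplot(tc, ggplot2::aes(x = .data$time_min,
                                        y = .data$activity_pct)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_line(data = grid, colour = "grey30") +
    ggplot2::labs(x = "Preincubation time (min)",
                  y = "Residual activity (%)",
                  title = sprintf("%sexponential decay fit",
                                  if (object$model == "mono") "Mono" else "Bi")) +
    ggplot2::theme_minimal()
  if (semilog) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

#' Plot a rate-vs-substrate table with its linear fit
#'
#' @param rates A data frame with columns `S0_M`, `v_M_per_min`.
#' @param fit Optional `bimolecular_fit` whose line is overlaid.
#' @return A ggplot object.
#' @export
plot_rate_linearity <- function(rates, fit = NULL) {
  p <- ggplot2::ggplot(as_tibble(rates),
                       ggplot2::aes(x = .data$S0_M, y = .data$v_M_per_min)) +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "[Substrate] (M)", y = "Rate (M/min)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(intercept = fit$intercept,
                                  slope = fit$k_bi * fit$E0,
                                  colour = "grey30")
  }
  p
}
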