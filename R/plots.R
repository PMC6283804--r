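# ggplot2 graphics for fits, TACs and the protocol study.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_errorbar
#'   geom_boxplot geom_hline labs scale_y_log10 facet_wrap autoplot
NULL

#' Plot a mono-exponential fit over its samples
#'
#' @param object A `monoexp_fit`.
#' @param ... Unused.
#' @return A ggplot (log-scaled y axis).
#' @export
autoplot.monoexp_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(time_h = seq(min(d$time_h), max(d$time_h), length.out = 100))
  grid$value <- predict(object, grid$time_h)
  ggplot(d, aes(x = .data$time_h, y = .data$value)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point() +
    scale_y_log10() +
    labs(x = "Time post-injection (h)", y = "Count rate (relative)",
         title = sprintf("T_eff = %.2f h,  R² = %.3f",
                         object$T_eff_h, object$r_squared))
}

#' Plot relative time-activity curves per region
#'
#' @param tacs Tidy TAC tibble (`region`, `time_h`, `rate`, optional
#'   `sigma`).
#' @return A ggplot, one panel per region, log-scaled rates.
#' @export
plot_tacs <- function(tacs) {
  p <- ggplot(tacs, aes(x = .data$time_h, y = .data$rate)) +
    geom_point() +
    geom_line(linetype = "dashed", colour = "grey50") +
    scale_y_log10() +
    facet_wrap(~region, scales = "free_y") +
    labs(x = "Time post-injection (h)", y = "Geometric-mean count rate (cps)")
  if ("sigma" %in% names(tacs)) {
    p <- p + geom_errorbar(aes(ymin = .data$rate - .data$sigma,
                               ymax = .data$rate + .data$sigma), width = 0.5)
  }
  p
}

#' Box plots of protocol percent differences
#'
#' Distribution of the TIAC percent differences of each reduced protocol
#' against the three-point reference, in the style of the sparsification
#' study (whiskers at 1.5 IQR).
#'
#' @param comparison Output of [compare_protocols()].
#' @return A ggplot.
#' @export
plot_protocol_differences <- function(comparison) {
  ggplot(comparison, aes(x = .data$protocol, y = .data$pct_diff)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_boxplot(coef = 1.5) +
    labs(x = NULL, y = "TIAC difference vs reference (%)")
}
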