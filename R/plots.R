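#' Plot conditional item response functions
#'
#' One panel per item, one curve per prior-response condition (items
#' without lag terms have a single curve). A positive lag coefficient shows
#' as a leftward shift of the success-conditional curve.
#'
#' @param model An [arirt_model()].
#' @param theta Ability grid (default `[-4, 4]` in 161 steps).
#' @return A ggplot object.
#' @export
plot_irf <- function(model, theta = seq(-4, 4, length.out = 161)) {
  tab <- irf_table(model, theta)
  ggplot2::ggplot(tab, ggplot2::aes(.data$theta, .data$probability,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~item, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(theta), y = "P(correct)",
                  colour = "previous response(s)") +
    ggplot2::theme_minimal()
}

#' Plot conditional item information functions
#'
#' @inheritParams plot_irf
#' @return A ggplot object.
#' @export
plot_information <- function(model, theta = seq(-4, 4, length.out = 161)) {
  tab <- irf_table(model, theta)
  ggplot2::ggplot(tab, ggplot2::aes(.data$theta, .data$information,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~item, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(theta), y = "information",
                  colour = "previous response(s)") +
    ggplot2::theme_minimal()
}

#' @method autoplot arirt_model
#' @export
autoplot.arirt_model <- function(object, type = c("irf", "information"),
                                 theta = seq(-4, 4, length.out = 161), ...) {
  type <- match.arg(type)
  if (type == "irf") plot_irf(object, theta) else plot_information(object, theta)
}

#' @method autoplot arirt_fit
#' @export
autoplot.arirt_fit <- function(object, type = c("irf", "information"), ...) {
  autoplot(object$model, type = type, ...)
}

#' @method autoplot arirt_study
#' @export
autoplot.arirt_study <- function(object, ...) {
  reps <- object$replicates
  ggplot2::ggplot(reps, ggplot2::aes(.data$p.value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = 2) +
    ggplot2::labs(x = "likelihood-ratio test p-value", y = "replicates") +
    ggplot2::theme_minimal()
}
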