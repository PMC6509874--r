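#' Plot an isobologram against the Loewe additivity line
#'
#' Equal-effect dose points \eqn{(f_1, f_2)} with the additivity line
#' \eqn{f_1 + f_2 = 1}; points below the line indicate synergy, above it
#' antagonism.
#'
#' @param object An `isobologram` from [ci_isobologram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isobologram <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$f1, y = .data$f2)) +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$ci), size = 2.5) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_colour_gradient2(midpoint = 1, low = "#2166ac",
                                    mid = "grey50", high = "#b2182c",
                                    name = "CI") +
    ggplot2::labs(
      title = sprintf("%s + %s (%s)", object$pair[1], object$pair[2],
                      object$category),
      x = sprintf("fractional dose of %s", object$pair[1]),
      y = sprintf("fractional dose of %s", object$pair[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot the target sensitivity ranking of a screen report
#'
#' Relative effective perturbations \eqn{\Delta E_i / E_{di}} per target on a
#' log scale, coloured by classification, with the sensitivity threshold `a`
#' drawn as a dashed line.
#'
#' @param object A `screen_report` from [screen_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, ...) {
  d <- dplyr::filter(object$targets, !is.na(.data$ratio))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$target, .data$ratio),
    y = .data$ratio, fill = .data$classification
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$config$a, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Delta * E[i] / E[di]),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
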