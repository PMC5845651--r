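#' Plot methods
#'
#' ggplot2 autoplot methods for the package's result objects.
#'
#' @param object A fitted/result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplots
NULL

#' @rdname autoplots
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  grid <- tibble::tibble(delta = seq(min(object$bins$delta_mean),
                                     max(object$bins$delta_mean),
                                     length.out = 200))
  grid$p <- predict(object, grid$delta)
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$delta_mean,
                                            y = .data$p_right)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.3) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$delta,
                                                 y = .data$p),
                       color = "steelblue") +
    ggplot2::labs(x = "#R - #L towers", y = "P(choose right)",
                  title = sprintf("Psychometric curve (slope %.1f %%/tower)",
                                  100 * object$slope)) +
    ggplot2::ylim(0, 1)
}

#' @rdname autoplots
#' @export
autoplot.spatial_logistic_fit <- function(object, ...) {
  d <- object$coefficients[-1, , drop = FALSE]
  mids <- (head(object$edges, -1) + tail(object$edges, -1)) / 2
  d$y_cm <- mids
  ggplot2::ggplot(d, ggplot2::aes(x = .data$y_cm, y = .data$estimate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$sd,
                                        ymax = .data$estimate + .data$sd),
                           width = 4) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cue region position (cm)",
                  y = "evidence weight",
                  title = "Spatial evidence weights")
}

#' @rdname autoplots
#' @export
autoplot.decoder_result <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$accuracy_percent), ],
                  ggplot2::aes(x = .data$y, y = .data$accuracy_percent)) +
    ggplot2::geom_hline(yintercept = 50, linetype = 2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "maze position (cm)",
                  y = "choice decoding accuracy (%)",
                  title = "Choice decoding from view angle")
}

#' @rdname autoplots
#' @export
autoplot.sdt_fit <- function(object, ...) {
  ggplot2::ggplot(object$sigmas, ggplot2::aes(x = .data$count,
                                              y = .data$sigma)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "tower count", y = expression(sigma),
                  title = sprintf("Perceptual noise vs count (%s form)",
                                  object$form))
}

#' @rdname autoplots
#' @export
autoplot.model_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = .data$model, y = .data$mi)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "model information (bits/trial)",
                  title = "Cross-validated model comparison")
}
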