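#' Plot methods
#'
#' `autoplot()` visualisations for the main result types: the
#' cross-validation deviance curve, bootstrap inclusion frequencies, and
#' per-sample RPI scores against the classification threshold.
#'
#' @param object A result object.
#' @param truth Optional binary truth vector (aligned to samples) colouring
#'   the RPI score plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name rpindex-plots
NULL

#' @rdname rpindex-plots
#' @export
autoplot.enet_cv <- function(object, ...) {
  d <- object$metrics
  ggplot2::ggplot(d, ggplot2::aes(x = log(.data$lambda), y = .data$mean_deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_deviance - .data$se_deviance,
                                      ymax = .data$mean_deviance + .data$se_deviance),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(c(object$lambda_min, object$lambda_1se)),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "CV binomial deviance",
                  title = sprintf("%d-fold cross-validation (alpha = %.2f)",
                                  object$n_folds, object$alpha))
}

#' @rdname rpindex-plots
#' @export
autoplot.stability_result <- function(object, ...) {
  d <- dplyr::arrange(object$markers, dplyr::desc(.data$frequency))
  d <- utils::head(d, 40)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$term,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$inclusion_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("bootstrap inclusion frequency (of %d)",
                              object$n_bootstraps),
                  y = NULL, fill = "selected",
                  title = "Stability selection")
}

#' @rdname rpindex-plots
#' @export
autoplot.rpi_result <- function(object, truth = NULL, ...) {
  d <- tibble::as_tibble(object)
  d$index <- seq_len(nrow(d))
  thr <- attr(object, "threshold") %||% 0.5
  if (!is.null(truth)) d$group <- factor(ifelse(truth == 1, "RP ≥ 2", "RP < 2"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$rpi)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "sample", y = "RPI score", colour = NULL,
                  title = "Radiation Pneumonitis Index")
  if (is.null(truth)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
    ggplot2::scale_colour_manual(values = c("RP < 2" = "#2e7d32",
                                            "RP ≥ 2" = "#c62828"))
}

#' @importFrom rlang .data
NULL
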