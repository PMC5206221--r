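#' Plot the charge-class univariate study
#'
#' Scatter of log Kd against the predictor, faceted by charge class with
#' a combined panel, each with its fitted regression line.
#'
#' @param object A [run_univariate_experiment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kd_univariate_experiment <- function(object, ...) {
  data <- object$data
  pred <- object$predictor
  combined <- dplyr::mutate(data, panel = "combined")
  by_class <- dplyr::mutate(data, panel = .data$charge_class)
  plot_data <- dplyr::bind_rows(by_class, combined)
  lines <- dplyr::rename(object$summary, panel = "charge_class")
  ggplot2::ggplot(plot_data,
                  ggplot2::aes(x = .data[[pred]], y = .data$log_kd)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         colour = "steelblue") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = pred, y = "log Kd (L/kg)",
                  title = "Univariate sorption models by charge class")
}

#' Plot an experiment report
#'
#' Per-split training and test performance (MUE and R2), one panel per
#' metric, coloured by hidden-node count when present.
#'
#' @param object A `kd_experiment_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kd_experiment_report <- function(object, ...) {
  tbl <- object$splits
  long <- tbl |>
    tidyr::pivot_longer(dplyr::any_of(c("mue_train", "mue_test",
                                        "r2_train", "r2_test")),
                        names_to = "metric", values_to = "value")
  aes <- if ("n_hidden" %in% names(tbl)) {
    ggplot2::aes(x = .data$split, y = .data$value,
                 colour = factor(.data$n_hidden))
  } else {
    ggplot2::aes(x = .data$split, y = .data$value)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "split", y = NULL, colour = "hidden nodes",
                  title = sprintf("%s experiment", object$method))
}

#' Plot an ARD relevance ranking
#'
#' @param object An [ard_ranking()] tibble.
#' @param top_n Number of descriptors shown (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kd_ard_ranking <- function(object, top_n = 10L, ...) {
  top <- head(object, top_n)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$mean_rank,
                                    y = stats::reorder(.data$term,
                                                       -.data$mean_rank))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean ARD rank across committee members (lower = more relevant)",
                  y = NULL, title = "Descriptor relevance (ARD)")
}

#' Observed versus predicted log Kd
#'
#' @param data A descriptor table.
#' @param model Any sorbkd model with a `predict` method.
#' @return A ggplot of predictions against observations with the
#'   identity line.
#' @export
plot_observed_predicted <- function(data, model) {
  pred <- predict(model, data)
  df <- tibble::tibble(observed = data$log_kd, predicted = as.numeric(pred),
                       charge_class = data$charge_class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$charge_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed log Kd", y = "predicted log Kd",
                  colour = "charge class")
}
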