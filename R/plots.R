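#' Plot per-fold cross-validation scores
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("%d-fold cross-validation", object$folds)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the Y-randomization score distribution
#'
#' Histogram of permuted-label accuracies with the unpermuted model's
#' accuracy marked; a real model should sit far right of the permuted mass.
#'
#' @param object a `yrand_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.yrand_result <- function(object, ...) {
  obs <- attr(object, "observed")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey60") +
    ggplot2::geom_vline(xintercept = obs$accuracy, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "accuracy under permuted labels",
                  y = "count",
                  title = "Y-randomization",
                  subtitle = "red line: unpermuted cross-validated accuracy") +
    ggplot2::theme_minimal()
}

#' Plot GA fitness across generations
#'
#' @param object a `ga_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("best_fitness", "mean_fitness"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness (CV balanced accuracy)",
                  title = "Genetic-algorithm feature selection") +
    ggplot2::theme_minimal()
}

#' Leverage values with the domain threshold
#'
#' The leverage half of a Williams plot: training leverages in order, with
#' the `h* = 3(p+1)/n` cut-off.
#'
#' @param object an `ad_leverage` model.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ad_leverage <- function(object, ...) {
  df <- tibble::tibble(index = seq_along(object$h_train),
                       h = object$h_train)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$h)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "training molecule", y = "leverage h",
                  title = sprintf("leverage applicability domain (h* = %.3f)",
                                  object$threshold)) +
    ggplot2::theme_minimal()
}
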