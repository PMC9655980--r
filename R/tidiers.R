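#' Tidy a fitted KNN model
#'
#' @param x a `knn_model`.
#' @param ... unused.
#' @return One row per training class with its count.
#' @export
tidy.knn_model <- function(x, ...) {
  tibble::tibble(
    class = x$levels,
    n_train = vapply(x$levels, function(l) sum(x$y == l), integer(1))
  )
}

#' @rdname tidy.knn_model
#' @return `glance()`: one row with `k`, `metric`, `n_train`, `n_features`,
#'   `standardized`.
#' @export
glance.knn_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, metric = x$metric, n_train = nrow(x$x),
    n_features = ncol(x$x), standardized = !is.null(x$std)
  )
}

#' Tidy a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return Long tibble of per-fold scores (`fold`, `metric`, `value`).
#' @export
tidy.cv_result <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold, -"fold",
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.cv_result
#' @return `glance()`: one row of pooled out-of-fold scores.
#' @export
glance.cv_result <- function(x, ...) {
  out <- tibble::as_tibble(x$pooled)
  out$folds <- x$folds
  out$seed <- x$seed
  out
}

#' Tidy a GA feature-selection run
#'
#' @param x a `ga_result`.
#' @param ... unused.
#' @return The per-generation history tibble.
#' @export
tidy.ga_result <- function(x, ...) x$history

#' @rdname tidy.ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness, n_selected = length(x$best_idx),
    generations = x$config$generations, population = x$config$population,
    seed = x$config$seed
  )
}

#' Tidy a Y-randomization result
#'
#' @param x a `yrand_result`.
#' @param ... unused.
#' @return The tibble of permuted scores.
#' @export
tidy.yrand_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.yrand_result
#' @export
glance.yrand_result <- function(x, ...) {
  obs <- attr(x, "observed")
  tibble::tibble(
    n_iter = nrow(x),
    mean_permuted_accuracy = mean(x$accuracy),
    sd_permuted_accuracy = stats::sd(x$accuracy),
    observed_accuracy = obs$accuracy,
    observed_balanced_accuracy = obs$balanced_accuracy
  )
}
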