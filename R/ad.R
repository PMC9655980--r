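#' Leverage applicability domain
#'
#' The leverage of a query with feature row `x` is
#' `h = x* (X'X)^-1 x*'` with the intercept-augmented training matrix `X`;
#' a query is inside the domain iff `h <= h*`, with the conventional
#' Williams-plot threshold `h* = 3 (p + 1) / n`.
#'
#' @param x_train standardized training descriptor matrix (columns linearly
#'   independent; run [variable_reduction()] first if not).
#' @param threshold override for `h*`.
#' @return An object of class `ad_leverage` with the projection matrix, the
#'   threshold and the training leverages.
#' @export
leverage_fit <- function(x_train, threshold = NULL) {
  X <- cbind(`(Intercept)` = 1, as.matrix(x_train))
  xtx <- crossprod(X)
  inv <- tryCatch(solve(xtx), error = function(e) {
    stop("X'X is singular (collinear features); ",
         "apply variable_reduction() first", call. = FALSE)
  })
  h_train <- rowSums((X %*% inv) * X)
  p <- ncol(x_train)
  n <- nrow(x_train)
  structure(
    list(inv = inv, threshold = threshold %||% 3 * (p + 1) / n,
         h_train = h_train, p = p, n = n),
    class = "ad_leverage"
  )
}

#' @rdname leverage_fit
#' @param ad an `ad_leverage` object.
#' @param x query feature matrix (same columns as the training matrix).
#' @return `leverage_value()`: tibble with `h` and `inside`.
#' @export
leverage_value <- function(ad, x) {
  X <- cbind(1, as.matrix(x))
  h <- rowSums((X %*% ad$inv) * X)
  tibble::tibble(h = h, inside = h <= ad$threshold)
}

#' Distance-based applicability domain
#'
#' A query's domain score is its mean distance to the `k_ad` nearest
#' training molecules; the inclusion threshold is the given percentile of
#' the training molecules' own scores (computed leave-self-out).
#'
#' @param x_train training feature matrix.
#' @param metric `"euclidean"` or `"jaccard_tanimoto"`.
#' @param k_ad number of neighbours averaged (default 5).
#' @param percentile threshold percentile of training scores (default 0.95).
#' @return An object of class `ad_distance`.
#' @export
distance_ad_fit <- function(x_train, metric = c("euclidean",
                                                "jaccard_tanimoto"),
                            k_ad = 5L, percentile = 0.95) {
  metric <- match.arg(metric)
  x_train <- as.matrix(x_train)
  model <- list(x = x_train, metric = metric,
                k_ad = min(k_ad, nrow(x_train) - 1L),
                percentile = percentile)
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(x_train))
  } else {
    tanimoto_cross(x_train, x_train)
  }
  diag(d) <- Inf # leave-self-out
  dbar <- apply(d, 1L, function(row) {
    mean(sort(row)[seq_len(model$k_ad)])
  })
  model$threshold <- unname(stats::quantile(dbar, percentile))
  model$dbar_train <- dbar
  structure(model, class = "ad_distance")
}

#' @rdname distance_ad_fit
#' @param ad an `ad_distance` object.
#' @param x query feature matrix.
#' @return `distance_ad_value()`: tibble with `dbar` and `inside`.
#' @export
distance_ad_value <- function(ad, x) {
  x <- as.matrix(x)
  d <- if (ad$metric == "euclidean") {
    tr <- ad$x
    d2 <- outer(rowSums(x^2), rowSums(tr^2), `+`) - 2 * tcrossprod(x, tr)
    sqrt(pmax(d2, 0))
  } else {
    tanimoto_cross(x, ad$x)
  }
  dbar <- apply(d, 1L, function(row) mean(sort(row)[seq_len(ad$k_ad)]))
  tibble::tibble(dbar = dbar, inside = dbar <= ad$threshold)
}

#' Consensus applicability domain: conjunction of member domains
#'
#' A molecule is inside the consensus domain only if it is inside the
#' domain of every member model.
#'
#' @param ... logical vectors (or a single list of them), one per member.
#' @return Logical vector.
#' @export
consensus_ad <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1L]]) &&
      !is.logical(members[[1L]])) {
    members <- members[[1L]]
  }
  if (length(members) == 0L) {
    stop("consensus_ad() needs at least one member result", call. = FALSE)
  }
  Reduce(`&`, members)
}
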