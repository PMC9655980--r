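#' Fit a k-nearest-neighbour classifier
#'
#' KNN is lazy: the training features and labels are stored in the model
#' and prediction ranks training molecules by distance to the query. Two
#' metrics are supported: `"jaccard_tanimoto"` for bit fingerprints and
#' `"euclidean"` for real-valued descriptors. Euclidean features are
#' standardized by default (mean/sd learned here) so that feature scales do
#' not dominate the distance; pass `standardize = FALSE` only when the
#' features are already on a common scale.
#'
#' @param x feature matrix (logical/0-1 for the Tanimoto metric).
#' @param y class labels (two levels).
#' @param k number of neighbours (1 <= k <= n).
#' @param metric `"euclidean"` or `"jaccard_tanimoto"`.
#' @param standardize standardize Euclidean features (ignored for
#'   fingerprints).
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(x, y, k = 5L,
                    metric = c("euclidean", "jaccard_tanimoto"),
                    standardize = TRUE) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  if (k < 1L || k > nrow(x)) {
    stop("k must be between 1 and the number of training molecules",
         call. = FALSE)
  }
  if (length(unique(y)) != 2L) {
    stop("labels must have exactly two classes", call. = FALSE)
  }
  std <- NULL
  if (metric == "euclidean") {
    if (standardize) {
      std <- standardize_fit(x)
      x <- standardize_apply(std, x)
    }
  } else {
    if (!all(x %in% c(0, 1))) {
      stop("the jaccard_tanimoto metric requires a 0/1 feature matrix",
           call. = FALSE)
    }
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  structure(
    list(x = x, y = y, k = as.integer(k), metric = metric, std = std,
         levels = sort(unique(y))),
    class = "knn_model"
  )
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k=%d, metric=%s, n=%d, classes={%s}\n",
              x$k, x$metric, nrow(x$x), paste(x$levels, collapse = ", ")))
  invisible(x)
}

knn_distances <- function(model, newx) {
  newx <- as.matrix(newx)
  if (model$metric == "euclidean") {
    if (!is.null(model$std)) newx <- standardize_apply(model$std, newx)
    tr <- model$x
    d2 <- outer(rowSums(newx^2), rowSums(tr^2), `+`) -
      2 * tcrossprod(newx, tr)
    sqrt(pmax(d2, 0))
  } else {
    tanimoto_cross(newx, model$x)
  }
}

#' Predict with a KNN model
#'
#' The predicted label is the majority class among the `k` nearest training
#' molecules. Ties are resolved deterministically: at the distance cut-off,
#' the training molecule with the first-sorting id is included; on a vote
#' tie (possible with even `k`), the class of the single nearest neighbour
#' wins. Set `exclude_self = TRUE` when re-predicting training rows to
#' leave each molecule's own stored copy out (the honest convention for
#' in-sample scoring; the default matches the common training-score
#' convention of including it at distance 0).
#'
#' @param object a `knn_model`.
#' @param newx feature matrix of query molecules.
#' @param exclude_self drop a zero-distance copy of the query from its own
#'   neighbour list (by row name match).
#' @param detail attach the per-query neighbour table (id, distance, class)
#'   for interpretability; disable for speed in tight loops.
#' @param ... unused.
#' @return A tibble with `.pred` and, when `detail = TRUE`, a `neighbors`
#'   list-column (tibbles of `id`, `distance`, `class`).
#' @export
predict.knn_model <- function(object, newx, exclude_self = FALSE,
                              detail = TRUE, ...) {
  d <- knn_distances(object, newx)
  ids <- rownames(object$x)
  qn <- rownames(as.matrix(newx))
  id_rank <- order(ids) # tie-break: first-sorting training id wins
  rank_of <- integer(length(ids))
  rank_of[id_rank] <- seq_along(ids)
  is_pos2 <- object$y == object$levels[2L]
  labs <- character(nrow(d))
  nbrs_list <- if (detail) vector("list", nrow(d)) else NULL
  for (i in seq_len(nrow(d))) {
    di <- d[i, ]
    keep <- seq_along(di)
    if (exclude_self && !is.null(qn) && qn[i] %in% ids) {
      keep <- keep[ids[keep] != qn[i]]
    }
    ord <- keep[order(di[keep], rank_of[keep])]
    sel <- ord[seq_len(min(object$k, length(ord)))]
    n2 <- sum(is_pos2[sel])
    n1 <- length(sel) - n2
    labs[i] <- if (n1 == n2) {
      object$y[sel[1L]] # even-k tie: the nearest neighbour decides
    } else if (n1 > n2) object$levels[1L] else object$levels[2L]
    if (detail) {
      nbrs_list[[i]] <- tibble::tibble(
        id = ids[sel], distance = unname(di[sel]), class = object$y[sel]
      )
    }
  }
  out <- tibble::tibble(.pred = labs)
  if (detail) out$neighbors <- nbrs_list
  out
}

#' Majority-vote consensus classifier
#'
#' Combines two or more fitted classifiers that share a label set; the
#' consensus prediction is the majority of the member predictions. With an
#' odd member count ties cannot occur; with an even count a tie raises an
#' error unless `tie` selects a fallback member.
#'
#' @param members named list of fitted models (each with a `predict` method
#'   returning a `.pred` column).
#' @param tie `"error"` (default) or the name of the member whose vote wins
#'   ties.
#' @return An object of class `consensus_model`.
#' @export
consensus_model <- function(members, tie = "error") {
  stopifnot(length(members) >= 2L)
  if (is.null(names(members)) || any(!nzchar(names(members)))) {
    names(members) <- paste0("M", seq_along(members))
  }
  levs <- lapply(members, function(m) m$levels)
  if (length(unique(levs)) != 1L) {
    stop("consensus members must predict the same label set", call. = FALSE)
  }
  structure(list(members = members, tie = tie, levels = levs[[1L]]),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("<consensus_model> %d members: %s\n", length(x$members),
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}

#' Predict with a consensus model
#'
#' @param object a `consensus_model`.
#' @param newx_list named list of feature matrices, one per member (members
#'   may use different feature spaces), or a single matrix shared by all.
#' @param ... passed to member predict methods.
#' @return A tibble with the member votes and the consensus `.pred`.
#' @export
predict.consensus_model <- function(object, newx_list, ...) {
  if (!is.list(newx_list)) {
    newx_list <- stats::setNames(
      rep(list(newx_list), length(object$members)), names(object$members)
    )
  }
  votes <- lapply(names(object$members), function(nm) {
    predict(object$members[[nm]], newx_list[[nm]], ...)$.pred
  })
  names(votes) <- names(object$members)
  vm <- do.call(cbind, votes)
  pred <- apply(vm, 1L, function(v) {
    tab <- table(factor(v, levels = object$levels))
    if (tab[1L] == tab[2L]) {
      if (identical(object$tie, "error")) {
        stop("consensus vote tie with an even member count; ",
             "configure a tie rule", call. = FALSE)
      }
      v[[object$tie]]
    } else {
      names(tab)[which.max(tab)]
    }
  })
  out <- tibble::as_tibble(vm)
  out$.pred <- pred
  out
}
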