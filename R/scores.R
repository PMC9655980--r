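#' Confusion counts for binary predictions
#'
#' @param truth,estimate label vectors of equal length.
#' @param positive the positive class label (for the BBB endpoint, BBB+).
#' @return A tibble with `TP`, `FP`, `TN`, `FN`, `positive`.
#' @export
confusion_counts <- function(truth, estimate, positive) {
  stopifnot(length(truth) == length(estimate))
  truth_pos <- truth == positive
  est_pos <- estimate == positive
  tibble::tibble(
    TP = sum(truth_pos & est_pos), FP = sum(!truth_pos & est_pos),
    TN = sum(!truth_pos & !est_pos), FN = sum(truth_pos & !est_pos),
    positive = positive
  )
}

#' Classification scores: sensitivity, specificity, accuracy, balanced accuracy
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/n`,
#' `BA = (Sn+Sp)/2`. If a class is absent from `truth` the corresponding
#' rate is `NA` with a warning.
#'
#' @inheritParams confusion_counts
#' @return A one-row tibble of class `score_report` with the four scores;
#'   the confusion counts are kept in the `confusion` attribute.
#' @export
#' @examples
#' classification_scores(c("+", "+", "-"), c("+", "-", "-"), positive = "+")
classification_scores <- function(truth, estimate, positive) {
  cc <- confusion_counts(truth, estimate, positive)
  if (cc$TP + cc$FN == 0L || cc$TN + cc$FP == 0L) {
    warning("a class is absent from the truth labels; ",
            "its rate is undefined", call. = FALSE)
  }
  sn <- if (cc$TP + cc$FN > 0L) cc$TP / (cc$TP + cc$FN) else NA_real_
  sp <- if (cc$TN + cc$FP > 0L) cc$TN / (cc$TN + cc$FP) else NA_real_
  n <- cc$TP + cc$FP + cc$TN + cc$FN
  out <- tibble::tibble(
    sensitivity = sn, specificity = sp,
    accuracy = (cc$TP + cc$TN) / n,
    balanced_accuracy = (sn + sp) / 2
  )
  attr(out, "confusion") <- cc
  class(out) <- c("score_report", class(out))
  out
}

#' Seeded stratified fold assignment
#'
#' Class proportions are preserved in every fold; fold sizes differ by at
#' most one per class.
#'
#' @param y label vector.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Integer fold id per observation.
#' @export
stratified_folds <- function(y, folds = 5L, seed = 1L) {
  stopifnot(folds >= 2L, length(y) >= folds)
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' k-fold cross-validation of a classifier
#'
#' Stratified, seeded partition; every observation is predicted exactly once
#' by a model fitted without it. The default model is the package KNN;
#' any fit/predict pair with the same signature can be cross-validated.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param positive positive class label.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param fit `function(x, y) -> model`.
#' @param predict_fun `function(model, newx) -> character predictions`.
#' @return An object of class `cv_result`: list with `per_fold` (tibble of
#'   fold scores), `pooled` (a `score_report` over all out-of-fold
#'   predictions), `predictions` (tibble `row`, `fold`, `truth`, `pred`),
#'   `folds`, `seed`.
#' @export
cross_validate <- function(x, y, positive, folds = 5L, seed = 1L,
                           fit = function(x, y) knn_fit(x, y, k = 5L),
                           predict_fun = function(m, newx) {
                             predict(m, newx, detail = FALSE)$.pred
                           }) {
  y <- as.character(y)
  fold_id <- stratified_folds(y, folds, seed)
  preds <- character(length(y))
  per_fold <- list()
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    if (length(unique(y[te])) < 2L) {
      warning("fold ", f, " does not contain both classes", call. = FALSE)
    }
    m <- fit(x[tr, , drop = FALSE], y[tr])
    p <- predict_fun(m, x[te, , drop = FALSE])
    preds[te] <- p
    per_fold[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f),
      suppressWarnings(classification_scores(y[te], p, positive))
    )
  }
  structure(
    list(
      per_fold = dplyr::bind_rows(per_fold),
      pooled = classification_scores(y, preds, positive),
      predictions = tibble::tibble(row = seq_along(y), fold = fold_id,
                                   truth = y, pred = preds),
      folds = folds, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold; pooled accuracy %.3f, BA %.3f\n",
              x$folds, x$pooled$accuracy, x$pooled$balanced_accuracy))
  invisible(x)
}

#' Y-randomization (response permutation) test
#'
#' The labels are permuted `n_iter` times; the model is refitted and
#' cross-validated on each permutation. A real structure-activity
#' relationship should score clearly above the permuted distribution, which
#' collapses towards the majority-class rate.
#'
#' @inheritParams cross_validate
#' @param n_iter number of permutations.
#' @return An object of class `yrand_result`: tibble of permuted scores
#'   (`iteration`, `accuracy`, `balanced_accuracy`) with the unpermuted CV
#'   scores in the `observed` attribute.
#' @export
y_randomization <- function(x, y, positive, n_iter = 20L, folds = 5L,
                            seed = 1L,
                            fit = function(x, y) knn_fit(x, y, k = 5L),
                            predict_fun = function(m, newx) {
                              predict(m, newx, detail = FALSE)$.pred
                            }) {
  stopifnot(n_iter >= 1L)
  y <- as.character(y)
  observed <- cross_validate(x, y, positive, folds, seed, fit, predict_fun)
  perms <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) sample(y))
  })
  rows <- lapply(seq_len(n_iter), function(i) {
    cv <- suppressWarnings(
      cross_validate(x, perms[[i]], positive, folds, seed + i, fit,
                     predict_fun)
    )
    tibble::tibble(
      iteration = i,
      accuracy = cv$pooled$accuracy,
      balanced_accuracy = cv$pooled$balanced_accuracy
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "observed") <- observed$pooled
  class(out) <- c("yrand_result", class(out))
  out
}
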