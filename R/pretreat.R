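#' Learn a column standardization on training rows
#'
#' Per-feature mean and standard deviation estimated on the training rows
#' only; [standardize_apply()] then centres and scales any row set with the
#' training parameters (so test data never leaks into the pretreatment).
#'
#' @param features numeric matrix (rows = molecules, columns = features).
#' @param train_rows row indices or rownames to learn from (default: all).
#' @return An object of class `standardization` with `mean` and `sd`.
#' @export
standardize_fit <- function(features, train_rows = seq_len(nrow(features))) {
  x <- features[train_rows, , drop = FALSE]
  stopifnot(nrow(x) >= 2L)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  if (any(sd < 1e-12)) {
    stop("zero-variance feature(s): ",
         paste(colnames(x)[sd < 1e-12], collapse = ", "),
         "; remove them first with variable_reduction()", call. = FALSE)
  }
  structure(list(mean = mu, sd = sd), class = "standardization")
}

#' @rdname standardize_fit
#' @param std a `standardization` object.
#' @return `standardize_apply()`: the transformed matrix.
#' @export
standardize_apply <- function(std, features) {
  stopifnot(inherits(std, "standardization"),
            ncol(features) == length(std$mean))
  sweep(sweep(features, 2L, std$mean), 2L, std$sd, `/`)
}

#' Remove constant, quasi-constant and highly correlated features
#'
#' Missing values are handled first according to `missing_policy`
#' (`"drop_feature"` removes columns containing any `NA`, `"drop_molecule"`
#' removes rows). Then constant columns are dropped, columns with standard
#' deviation below `quasi_constant_sd` are dropped, and for each pair with
#' absolute Pearson correlation above `correlation_threshold` the
#' later column is dropped.
#'
#' @param features numeric matrix.
#' @param drop_constant drop zero-variance columns (default TRUE).
#' @param quasi_constant_sd drop columns with sd below this (default 0,
#'   i.e. disabled beyond exact constants).
#' @param correlation_threshold absolute pairwise correlation above which
#'   the later column of a pair is dropped (default `NULL` = disabled).
#' @param missing_policy `"drop_feature"` or `"drop_molecule"`.
#' @return The reduced matrix; attribute `reduction_log` is a tibble of
#'   `item`, `kind`, `reason`.
#' @export
variable_reduction <- function(features, drop_constant = TRUE,
                               quasi_constant_sd = 0,
                               correlation_threshold = NULL,
                               missing_policy = c("drop_feature",
                                                  "drop_molecule")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(nrow(features) > 0L, ncol(features) > 0L)
  log <- list()
  note <- function(item, kind, reason) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      item = item, kind = kind, reason = reason
    )
  }
  if (anyNA(features)) {
    if (missing_policy == "drop_feature") {
      bad <- colnames(features)[colSums(is.na(features)) > 0L]
      for (b in bad) note(b, "feature", "missing values")
      features <- features[, !colnames(features) %in% bad, drop = FALSE]
    } else {
      bad <- which(rowSums(is.na(features)) > 0L)
      for (b in rownames(features)[bad] %||% as.character(bad)) {
        note(b, "molecule", "missing values")
      }
      if (length(bad) > 0L) features <- features[-bad, , drop = FALSE]
    }
  }
  sds <- apply(features, 2L, stats::sd)
  if (drop_constant) {
    bad <- colnames(features)[sds < 1e-12]
    for (b in bad) note(b, "feature", "constant")
    features <- features[, sds >= 1e-12, drop = FALSE]
    sds <- sds[sds >= 1e-12]
  }
  if (quasi_constant_sd > 0) {
    bad <- colnames(features)[sds < quasi_constant_sd]
    for (b in bad) note(b, "feature", "quasi-constant")
    features <- features[, sds >= quasi_constant_sd, drop = FALSE]
  }
  if (!is.null(correlation_threshold) && ncol(features) >= 2L) {
    r <- abs(stats::cor(features))
    drop <- rep(FALSE, ncol(features))
    for (j in 2:ncol(features)) {
      if (any(r[seq_len(j - 1L), j] > correlation_threshold & !drop[seq_len(j - 1L)])) {
        drop[j] <- TRUE
        note(colnames(features)[j], "feature", "correlated with earlier feature")
      }
    }
    features <- features[, !drop, drop = FALSE]
  }
  if (ncol(features) == 0L) {
    stop("variable reduction removed every feature", call. = FALSE)
  }
  attr(features, "reduction_log") <- if (length(log) > 0L) {
    dplyr::bind_rows(log)
  } else tibble::tibble(item = character(), kind = character(),
                        reason = character())
  features
}
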