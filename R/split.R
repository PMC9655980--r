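#' Split a dataset into training and test sets
#'
#' Three strategies: `random` (seeded shuffle, `train_prop` of rows to
#' training), `venetian` (every `every_n`-th row to the test set, a
#' venetian-blinds rule), and `by_variable` (rows with a non-empty value in
#' `variable` go to training, the rest to test — the rule used to split on
#' the presence of a PubChem CID).
#'
#' @param table a data frame with an `id` column.
#' @param method `"random"`, `"venetian"` or `"by_variable"`.
#' @param train_prop training proportion for `random` (default 0.8).
#' @param every_n period for `venetian` (default 5).
#' @param variable column name for `by_variable`.
#' @param seed integer seed (used by `random` only).
#' @return An object of class `data_split`: list with `train_ids`,
#'   `test_ids`, `method`, `params`, `seed`.
#' @export
#' @examples
#' split_dataset(tibble::tibble(id = 1:10), "venetian", every_n = 5)
split_dataset <- function(table, method = c("random", "venetian",
                                            "by_variable"),
                          train_prop = 0.8, every_n = 5L, variable = NULL,
                          seed = 1L) {
  method <- match.arg(method)
  ids <- table$id
  n <- length(ids)
  stopifnot(n >= 2L)
  if (method == "random") {
    stopifnot(train_prop > 0, train_prop < 1)
    perm <- with_seed(seed, sample.int(n))
    n_train <- max(1L, min(n - 1L, round(train_prop * n)))
    train <- sort(ids[perm[seq_len(n_train)]])
    test <- sort(setdiff(ids, train))
  } else if (method == "venetian") {
    stopifnot(every_n >= 2L)
    test_pos <- seq_len(n) %% every_n == 0L
    train <- ids[!test_pos]
    test <- ids[test_pos]
  } else {
    stopifnot(!is.null(variable), variable %in% names(table))
    v <- table[[variable]]
    filled <- !is.na(v) & nzchar(trimws(as.character(v)))
    train <- ids[filled]
    test <- ids[!filled]
  }
  if (length(train) == 0L || length(test) == 0L) {
    stop("split produced an empty training or test set", call. = FALSE)
  }
  structure(
    list(train_ids = train, test_ids = test, method = method,
         params = list(train_prop = train_prop, every_n = every_n,
                       variable = variable),
         seed = seed),
    class = "data_split"
  )
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split %s> %d train / %d test\n", x$method,
              length(x$train_ids), length(x$test_ids)))
  invisible(x)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
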