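#' Group duplicate molecules by canonical key
#'
#' Computes the canonical key of every molecule under the given
#' ignore-options and returns the equivalence classes of size two or more.
#' Ignoring more features can only merge classes, never split them.
#'
#' @inheritParams canonical_key
#' @param table a molecule table.
#' @return A tibble with columns `group`, `id`, `key` (one row per member of
#'   a duplicated group); the options used are stored in the `options`
#'   attribute.
#' @export
#' @examples
#' tbl <- molecule_table(c("CCO", "OCC", "CCN"))
#' find_duplicates(tbl)
find_duplicates <- function(table, ignore_stereo = FALSE,
                            ignore_charge = FALSE, ignore_isotope = FALSE,
                            ignore_h_count = FALSE) {
  stopifnot(nrow(table) > 0L)
  keys <- purrr::map_chr(
    table$mol, canonical_key,
    ignore_stereo = ignore_stereo, ignore_charge = ignore_charge,
    ignore_isotope = ignore_isotope, ignore_h_count = ignore_h_count
  )
  df <- tibble::tibble(id = table$id, key = keys)
  groups <- df |>
    dplyr::add_count(.data$key) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::mutate(group = match(.data$key, unique(.data$key))) |>
    dplyr::select("group", "id", "key") |>
    dplyr::arrange(.data$group, .data$id)
  attr(groups, "options") <- list(
    ignore_stereo = ignore_stereo, ignore_charge = ignore_charge,
    ignore_isotope = ignore_isotope, ignore_h_count = ignore_h_count
  )
  groups
}

#' Resolve duplicate groups against an endpoint column
#'
#' Groups whose members disagree on the endpoint (or have a missing value)
#' are removed entirely; groups that agree keep their first member in file
#' order. Molecules outside any group are untouched.
#'
#' @param table a molecule table.
#' @param groups result of [find_duplicates()].
#' @param endpoint name of the endpoint column in `table`.
#' @return The reduced table, with a `removals` attribute (tibble of
#'   `id`, `reason`).
#' @export
resolve_duplicates <- function(table, groups, endpoint) {
  if (!endpoint %in% names(table)) {
    stop("endpoint column '", endpoint, "' not found", call. = FALSE)
  }
  removals <- list()
  for (g in unique(groups$group)) {
    ids <- groups$id[groups$group == g]
    vals <- table[[endpoint]][match(ids, table$id)]
    if (anyNA(vals) || length(unique(vals)) > 1L) {
      removals[[length(removals) + 1L]] <- tibble::tibble(
        id = ids,
        reason = if (anyNA(vals)) "duplicate group with missing endpoint"
        else "duplicate group with conflicting endpoint"
      )
    } else {
      removals[[length(removals) + 1L]] <- tibble::tibble(
        id = ids[-1L], reason = "duplicate of retained molecule"
      )
    }
  }
  rem <- if (length(removals) > 0L) dplyr::bind_rows(removals) else
    tibble::tibble(id = integer(), reason = character())
  out <- table[!table$id %in% rem$id, , drop = FALSE]
  attr(out, "removals") <- rem
  out
}
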