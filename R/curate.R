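#' Curation preset for the blood-brain-barrier dataset
#'
#' Runs the fixed curation recipe used for the BBB permeability endpoint:
#' kekulize every molecule (molecules with no valid Kekule assignment are
#' removed), then remove molecules with disconnected structures, unusual
#' valences and single-heavy-atom molecules, then group duplicates ignoring
#' stereochemistry and resolve them against the endpoint column (groups
#' with conflicting labels are dropped entirely; agreeing groups keep their
#' first member). Re-running the preset on its own output removes nothing.
#'
#' @param table a molecule table with an endpoint column.
#' @param endpoint name of the class-label column (default `"BBB"`).
#' @return The curated table. The attribute `removal_log` is a tibble with
#'   `id`, `step`, `reason`; `removal_counts` summarises per-step counts.
#' @export
curate_bbb <- function(table, endpoint = "BBB") {
  if (!endpoint %in% names(table)) {
    stop("endpoint column '", endpoint, "' not found", call. = FALSE)
  }
  log <- list()
  note <- function(ids, step, reason) {
    if (length(ids) > 0L) {
      log[[length(log) + 1L]] <<- tibble::tibble(
        id = ids, step = step, reason = reason
      )
    }
  }

  kek <- purrr::map(table$mol, function(m) {
    tryCatch(kekulize(m), error = function(e) e)
  })
  bad <- vapply(kek, inherits, logical(1), what = "error")
  note(table$id[bad], "kekulize", "no valid Kekule assignment")
  table <- table[!bad, , drop = FALSE]
  table$mol <- kek[!bad]

  checks <- check_structures(table, c("multiple_structures", "unusual_valence"))
  drop <- checks$id[checks$multiple_structures]
  note(drop, "check_structures", "disconnected structure")
  table <- table[!table$id %in% drop, , drop = FALSE]
  checks <- checks[!checks$id %in% drop, , drop = FALSE]

  drop <- checks$id[checks$unusual_valence]
  note(drop, "check_structures", "unusual valence")
  table <- table[!table$id %in% drop, , drop = FALSE]

  single <- vapply(table$mol, function(m) length(heavy_idx(m)) == 1L,
                   logical(1))
  note(table$id[single], "check_structures", "single-atom molecule")
  table <- table[!single, , drop = FALSE]

  if (nrow(table) > 0L) {
    groups <- find_duplicates(table, ignore_stereo = TRUE)
    if (nrow(groups) > 0L) {
      table <- resolve_duplicates(table, groups, endpoint)
      rem <- attr(table, "removals")
      note(rem$id, "resolve_duplicates", rem$reason)
    }
  }

  log_tbl <- if (length(log) > 0L) dplyr::bind_rows(log) else
    tibble::tibble(id = integer(), step = character(), reason = character())
  attr(table, "removal_log") <- log_tbl
  attr(table, "removal_counts") <- dplyr::count(log_tbl, .data$step,
                                                .data$reason)
  attr(table, "removals") <- NULL
  table
}
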