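PROJECT_FORMAT_VERSION <- "1.0"

#' Bundle fitted models into a portable project
#'
#' A project stores, for every member model, the fitted KNN (training
#' features, labels, k, metric, standardization), the feature recipe needed
#' to recompute its inputs for new molecules (descriptor names or
#' fingerprint parameters), and an optional applicability domain; plus an
#' optional majority-vote consensus over the members. A saved project is
#' plain JSON: transparent, diffable, and loading it executes no code.
#'
#' @param models named list of model entries from [project_model()].
#' @param endpoint endpoint name (e.g. `"BBB"`).
#' @param positive positive class label (e.g. `"BBB+"`).
#' @param consensus character vector of member names to combine by majority
#'   vote, or `NULL` for no consensus entry.
#' @param metadata free-form list (creation date and counts are added).
#' @return An object of class `qsar_project`.
#' @export
qsar_project <- function(models, endpoint, positive, consensus = NULL,
                         metadata = list()) {
  stopifnot(length(models) >= 1L, !is.null(names(models)))
  if (!is.null(consensus)) {
    stopifnot(all(consensus %in% names(models)), length(consensus) >= 2L)
  }
  metadata$created <- metadata$created %||% format(Sys.Date())
  metadata$n_models <- length(models)
  structure(
    list(version = PROJECT_FORMAT_VERSION, endpoint = endpoint,
         positive = positive, models = models, consensus = consensus,
         metadata = metadata),
    class = "qsar_project"
  )
}

#' @rdname qsar_project
#' @param model a fitted `knn_model`.
#' @param recipe feature recipe: `list(kind = "descriptors", names = ...)`,
#'   `list(kind = "maccs166")` or
#'   `list(kind = "ecfp", radius = ..., length = ...)`.
#' @param ad optional `ad_leverage` or `ad_distance` object.
#' @return `project_model()`: a model entry list.
#' @export
project_model <- function(model, recipe, ad = NULL) {
  stopifnot(inherits(model, "knn_model"),
            recipe$kind %in% c("descriptors", "maccs166", "ecfp"))
  list(model = model, recipe = recipe, ad = ad)
}

#' @export
print.qsar_project <- function(x, ...) {
  cat(sprintf(
    "<qsar_project v%s> endpoint %s (positive %s); models: %s%s\n",
    x$version, x$endpoint, x$positive, paste(names(x$models), collapse = ", "),
    if (!is.null(x$consensus)) {
      paste0("; consensus over ", paste(x$consensus, collapse = "+"))
    } else ""
  ))
  invisible(x)
}

# ---- (de)serialization ----------------------------------------------------

mat_out <- function(m) {
  list(values = unname(as.matrix(m)) * 1, rows = rownames(m),
       cols = colnames(m))
}

mat_in <- function(o, logical = FALSE) {
  m <- do.call(rbind, lapply(o$values, as.numeric))
  if (logical) m <- m > 0.5
  rownames(m) <- unlist(o$rows)
  colnames(m) <- unlist(o$cols)
  m
}

#' Save / load a project as JSON
#'
#' `load_project(save_project(p, f))` reproduces predictions bit-for-bit:
#' all numeric payloads are serialized at full precision. Loading a file
#' with a different format version fails with both versions named.
#'
#' @param project a `qsar_project`.
#' @param path file path (conventionally `.json`).
#' @return `save_project()`: `path` invisibly; `load_project()`: the
#'   reconstructed `qsar_project`.
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "qsar_project"))
  ser <- list(
    version = project$version, endpoint = project$endpoint,
    positive = project$positive, consensus = project$consensus,
    metadata = project$metadata,
    models = lapply(project$models, function(entry) {
      m <- entry$model
      list(
        k = m$k, metric = m$metric, levels = m$levels, y = m$y,
        x = mat_out(m$x),
        std = if (!is.null(m$std)) {
          list(mean = as.list(m$std$mean), sd = as.list(m$std$sd))
        },
        recipe = entry$recipe,
        ad = if (!is.null(entry$ad)) serialize_ad(entry$ad)
      )
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

serialize_ad <- function(ad) {
  if (inherits(ad, "ad_leverage")) {
    list(kind = "leverage", inv = mat_out(ad$inv), threshold = ad$threshold,
         p = ad$p, n = ad$n, h_train = ad$h_train)
  } else {
    list(kind = "distance", x = mat_out(ad$x), metric = ad$metric,
         k_ad = ad$k_ad, percentile = ad$percentile,
         threshold = ad$threshold, dbar_train = ad$dbar_train)
  }
}

deserialize_ad <- function(o) {
  if (o$kind == "leverage") {
    structure(
      list(inv = mat_in(o$inv), threshold = o$threshold, p = o$p, n = o$n,
           h_train = unlist(o$h_train)),
      class = "ad_leverage"
    )
  } else {
    structure(
      list(x = mat_in(o$x, logical = o$metric == "jaccard_tanimoto"),
           metric = o$metric, k_ad = o$k_ad, percentile = o$percentile,
           threshold = o$threshold, dbar_train = unlist(o$dbar_train)),
      class = "ad_distance"
    )
  }
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  ser <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("cannot load project from '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!identical(ser$version, PROJECT_FORMAT_VERSION)) {
    stop("project format version mismatch: file has '", ser$version %||% "?",
         "', this build reads '", PROJECT_FORMAT_VERSION, "'", call. = FALSE)
  }
  models <- lapply(ser$models, function(o) {
    logical_x <- o$metric == "jaccard_tanimoto"
    m <- structure(
      list(
        x = mat_in(o$x, logical = logical_x),
        y = unlist(o$y), k = o$k, metric = o$metric,
        std = if (!is.null(o$std)) {
          structure(list(mean = unlist(o$std$mean), sd = unlist(o$std$sd)),
                    class = "standardization")
        },
        levels = unlist(o$levels)
      ),
      class = "knn_model"
    )
    recipe <- o$recipe
    recipe$names <- if (!is.null(recipe$names)) unlist(recipe$names)
    list(model = m, recipe = recipe,
         ad = if (!is.null(o$ad)) deserialize_ad(o$ad))
  })
  names(models) <- names(ser$models)
  qsar_project(models, ser$endpoint, ser$positive,
               consensus = if (!is.null(ser$consensus)) unlist(ser$consensus),
               metadata = ser$metadata)
}

# ---- applying a project ---------------------------------------------------

recipe_features <- function(recipe, table) {
  if (recipe$kind == "descriptors") {
    dm <- calc_descriptor_matrix(table, recipe$names)
    m <- as.matrix(dm[, recipe$names, drop = FALSE])
    rownames(m) <- as.character(table$id)
    m
  } else if (recipe$kind == "maccs166") {
    m <- maccs166_matrix(table) * 1
    rownames(m) <- as.character(table$id)
    m
  } else {
    m <- ecfp_matrix(table, recipe$radius, recipe$length) * 1
    rownames(m) <- as.character(table$id)
    m
  }
}

#' Apply a project to a molecule table
#'
#' For every molecule and every bundled model: recompute the features the
#' model needs, apply the stored pretreatment, predict the class and
#' evaluate the applicability domain. Molecules whose features cannot be
#' computed for a model are flagged (`NA` prediction), never dropped. The
#' consensus column is the majority vote of the member predictions, and a
#' molecule is inside the consensus domain only if inside every member
#' domain.
#'
#' @param project a `qsar_project`.
#' @param table a molecule table.
#' @return A tibble: `id`, `smiles`, `mol`, then `<model>_pred` and
#'   `<model>_in_ad` per model, and `consensus_pred`/`consensus_in_ad` when
#'   the project defines one.
#' @export
run_project <- function(project, table) {
  out <- tibble::tibble(
    id = table$id,
    smiles = vapply(table$mol, write_smiles, character(1)),
    mol = table$mol
  )
  votes <- list()
  ad_flags <- list()
  for (nm in names(project$models)) {
    entry <- project$models[[nm]]
    feats <- recipe_features(entry$recipe, table)
    ok <- rowSums(is.na(feats)) == 0L
    pred <- rep(NA_character_, nrow(table))
    inside <- rep(NA, nrow(table))
    if (any(ok)) {
      pr <- predict(entry$model, feats[ok, , drop = FALSE], detail = FALSE)
      pred[ok] <- pr$.pred
      if (!is.null(entry$ad)) {
        q <- feats[ok, , drop = FALSE]
        if (inherits(entry$ad, "ad_leverage")) {
          if (!is.null(entry$model$std)) {
            q <- standardize_apply(entry$model$std, q)
          }
          inside[ok] <- leverage_value(entry$ad, q)$inside
        } else {
          inside[ok] <- distance_ad_value(entry$ad, q)$inside
        }
      }
    }
    out[[paste0(nm, "_pred")]] <- pred
    out[[paste0(nm, "_in_ad")]] <- inside
    votes[[nm]] <- pred
    ad_flags[[nm]] <- inside
  }
  if (!is.null(project$consensus)) {
    vm <- do.call(cbind, votes[project$consensus])
    levs <- project$models[[project$consensus[1L]]]$model$levels
    out$consensus_pred <- apply(vm, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(NA_character_)
      tab <- table(factor(v, levels = levs))
      if (tab[1L] == tab[2L]) NA_character_ else names(tab)[which.max(tab)]
    })
    out$consensus_in_ad <- consensus_ad(ad_flags[project$consensus])
  }
  out
}

#' Export a prediction table
#'
#' `tsv` writes a tab-separated table (id, SMILES, per-model predictions
#' and domain flags, consensus). `smiles` and `sdf` write molecule files
#' with the predictions embedded as properties/data fields.
#'
#' @param predictions result of [run_project()].
#' @param path output file.
#' @param format `"tsv"`, `"smiles"` or `"sdf"`.
#' @return `path`, invisibly.
#' @export
export_results <- function(predictions, path,
                           format = c("tsv", "smiles", "sdf")) {
  format <- match.arg(format)
  stopifnot(nrow(predictions) > 0L)
  if (format == "tsv") {
    flat <- predictions[, setdiff(names(predictions), "mol"), drop = FALSE]
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_molecules(predictions, path, format = format)
  }
  invisible(path)
}
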