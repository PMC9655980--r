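#' Read molecules from a SMILES or SDF file into a tidy molecule table
#'
#' The returned tibble has one row per molecule with columns `id` (1-based
#' file position), `smiles` (canonical-input spelling for SDF, the raw line
#' for SMILES files), `name`, the parsed graph in the list-column `mol`,
#' and one column per extra property (SDF data fields, or extra delimited
#' columns on each SMILES line). Unparseable entries are collected in the
#' `parse_errors` attribute (a tibble with `line`, `text`, `message`) and
#' reported as a warning, never silently dropped.
#'
#' @param path file path.
#' @param format `"smiles"` (one molecule per line, optional tab-separated
#'   extra columns) or `"sdf"` (MDL V2000).
#' @param header for SMILES files: does the first line name the columns?
#' @return A tibble (`mol` list-column of `mol_graph` objects).
#' @export
read_molecules <- function(path, format = c("smiles", "sdf"),
                           header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  tbl <- if (format == "smiles") {
    read_smiles_file(path, header = header)
  } else {
    read_sdf_file(path)
  }
  errs <- attr(tbl, "parse_errors")
  if (nrow(tbl) == 0L) {
    stop("no valid molecules in '", path, "'",
         if (!is.null(errs) && nrow(errs) > 0L) {
           paste0(" (", nrow(errs), " unparseable entries)")
         })
  }
  if (!is.null(errs) && nrow(errs) > 0L) {
    warning(nrow(errs), " entries could not be parsed (lines ",
            paste(errs$line, collapse = ", "), "); see attr(x, 'parse_errors')",
            call. = FALSE)
  }
  tbl
}

read_smiles_file <- function(path, header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  col_names <- NULL
  if (header && length(lines) > 0L) {
    col_names <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
    lines <- lines[-1L]
    offset <- 1L
  }
  keep <- nzchar(trimws(lines))
  recs <- list()
  errs <- list()
  for (k in which(keep)) {
    fields <- strsplit(lines[k], "[\t ]+")[[1]]
    smi <- fields[1L]
    mol <- tryCatch(parse_smiles(smi), error = function(e) e)
    if (inherits(mol, "error")) {
      errs[[length(errs) + 1L]] <- tibble::tibble(
        line = k + offset, text = lines[k], message = conditionMessage(mol)
      )
      next
    }
    extra <- if (length(fields) > 1L) fields[-1L] else character()
    nm <- if (length(extra) >= 1L && is.null(col_names)) extra[1L] else ""
    props <- if (is.null(col_names)) {
      if (length(extra) > 1L) {
        stats::setNames(as.list(extra[-1L]),
                        paste0("P", seq_along(extra[-1L])))
      } else list()
    } else {
      nms <- col_names[-1L][seq_along(extra)]
      p <- stats::setNames(as.list(extra), nms)
      if ("name" %in% nms) { # a literal name column is the molecule name
        nm <- p$name
        p$name <- NULL
      }
      p
    }
    mol$name <- nm
    recs[[length(recs) + 1L]] <- c(
      list(line = k + offset, smiles = smi, name = nm, mol = list(mol)), props
    )
  }
  tbl <- if (length(recs) > 0L) {
    dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  } else {
    tibble::tibble(line = integer(), smiles = character(),
                   name = character(), mol = list())
  }
  tbl <- dplyr::mutate(tbl, id = dplyr::row_number(), .before = 1L)
  tbl$line <- NULL
  attr(tbl, "parse_errors") <- if (length(errs) > 0L) {
    dplyr::bind_rows(errs)
  } else tibble::tibble(line = integer(), text = character(),
                        message = character())
  tbl
}

# -- MDL SDF V2000 ----------------------------------------------------------
# Implemented here because round-tripping formal charges requires the
# "M  CHG" property lines, which override the deprecated atom-line codes.

OLD_CHARGE_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                     `7` = -3L)

read_sdf_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- c(1L, which(lines == "$$$$") + 1L)
  starts <- starts[starts <= length(lines)]
  ends <- c(which(lines == "$$$$") - 1L, length(lines))[seq_along(starts)]
  recs <- list()
  errs <- list()
  entry_no <- 0L
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    if (all(!nzchar(trimws(block)))) next
    entry_no <- entry_no + 1L
    parsed <- tryCatch(parse_sdf_block(block), error = function(e) e)
    if (inherits(parsed, "error")) {
      errs[[length(errs) + 1L]] <- tibble::tibble(
        line = starts[k], text = block[1L], message = conditionMessage(parsed)
      )
      next
    }
    recs[[length(recs) + 1L]] <- c(
      list(smiles = write_smiles(parsed$mol),
           name = parsed$mol$name, mol = list(parsed$mol)),
      parsed$data
    )
  }
  tbl <- if (length(recs) > 0L) {
    dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  } else {
    tibble::tibble(smiles = character(), name = character(), mol = list())
  }
  tbl <- dplyr::mutate(tbl, id = dplyr::row_number(), .before = 1L)
  attr(tbl, "parse_errors") <- if (length(errs) > 0L) {
    dplyr::bind_rows(errs)
  } else tibble::tibble(line = integer(), text = character(),
                        message = character())
  tbl
}

parse_sdf_block <- function(block) {
  if (length(block) < 4L) stop("truncated SDF record")
  name <- trimws(block[1L])
  counts <- block[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || is.na(nb)) stop("bad counts line")
  atom_lines <- block[4L + seq_len(na)]
  bond_lines <- if (nb > 0L) block[4L + na + seq_len(nb)] else character()

  element <- trimws(substr(atom_lines, 32L, 34L))
  code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  charge <- unname(OLD_CHARGE_CODE[as.character(code)])
  charge[is.na(charge)] <- 0L
  parity <- suppressWarnings(as.integer(substr(atom_lines, 40L, 42L)))
  chiral <- rep(NA_character_, na)
  chiral[!is.na(parity) & parity == 1L] <- "@@"
  chiral[!is.na(parity) & parity == 2L] <- "@"
  atoms <- tibble::tibble(
    element = element, charge = as.integer(charge), isotope = NA_integer_,
    hcount = NA_integer_, aromatic = FALSE, chiral = chiral
  )
  bonds <- if (nb > 0L) {
    type <- as.integer(substr(bond_lines, 7L, 9L))
    tibble::tibble(
      from = as.integer(substr(bond_lines, 1L, 3L)),
      to = as.integer(substr(bond_lines, 4L, 6L)),
      order = ifelse(type == 4L, 1L, type),
      aromatic = type == 4L,
      stereo = NA_character_
    )
  } else empty_bonds()

  rest <- block[-seq_len(4L + na + nb)]
  # M CHG lines supersede all atom-line codes: if any appear, charges come
  # only from them (per the V2000 specification)
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines) > 0L) {
    atoms$charge <- 0L
    for (ln in chg_lines) {
      vals <- scan(text = substring(ln, 10L), quiet = TRUE)
      idx <- vals[c(TRUE, FALSE)]
      atoms$charge[idx] <- as.integer(vals[c(FALSE, TRUE)])
    }
  }
  for (ln in grep("^M  ISO", rest, value = TRUE)) {
    vals <- scan(text = substring(ln, 10L), quiet = TRUE)
    atoms$isotope[vals[c(TRUE, FALSE)]] <- as.integer(vals[c(FALSE, TRUE)])
  }

  mol <- new_mol_graph(atoms, bonds, name = name)
  mol$atoms$hcount <- implicit_hcount(mol)
  mol$atoms$hcount[mol$atoms$charge != 0L] <- pmax(
    0L, mol$atoms$hcount[mol$atoms$charge != 0L]
  )
  # charged atoms: fill to the charge-adjusted valence
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg) > 0L) {
    v <- valence_sum(mol)
    for (a in chg) {
      av <- allowed_valences(mol$atoms$element[a], mol$atoms$charge[a])
      fit <- av[!is.na(av) & av >= v[a]]
      mol$atoms$hcount[a] <- if (length(fit) > 0L) {
        as.integer(round(fit[1] - v[a]))
      } else 0L
    }
  }

  # undo the H-last MDL parity convention (our reference order puts the
  # implicit H slot first)
  flip <- !is.na(mol$atoms$chiral) & mol$atoms$hcount > 0L
  mol$atoms$chiral[flip] <- vapply(mol$atoms$chiral[flip], flip_tag,
                                   character(1))

  mend <- which(grepl("^M  END", rest))
  data_lines <- if (length(mend) > 0L) rest[-seq_len(mend[1L])] else character()
  data <- list()
  i <- 1L
  while (i <= length(data_lines)) {
    hdr <- data_lines[i]
    tag <- regmatches(hdr, regexec("^>.*<([^>]+)>", hdr))[[1]]
    if (length(tag) == 2L) {
      vals <- character()
      j <- i + 1L
      while (j <= length(data_lines) && nzchar(trimws(data_lines[j]))) {
        vals <- c(vals, data_lines[j])
        j <- j + 1L
      }
      data[[tag[2L]]] <- paste(vals, collapse = "\n")
      i <- j
    } else {
      i <- i + 1L
    }
  }
  mol$props <- data
  list(mol = mol, data = data)
}

#' Write a molecule table to a SMILES or SDF file
#'
#' The inverse of [read_molecules()]: property columns become tab-separated
#' columns (SMILES, with a header line) or data fields (SDF).
#'
#' @param table a molecule table (tibble with a `mol` list-column).
#' @param path output file path.
#' @param format `"smiles"` or `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(table, path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  stopifnot(nrow(table) > 0L, "mol" %in% names(table))
  prop_cols <- setdiff(names(table), c("id", "smiles", "name", "mol"))
  nm <- if ("name" %in% names(table)) table$name else rep("", nrow(table))
  if (format == "smiles") {
    hdr <- paste(c("smiles", "name", prop_cols), collapse = "\t")
    rows <- vapply(seq_len(nrow(table)), function(i) {
      paste(c(write_smiles(table$mol[[i]]),
              nm[i],
              vapply(prop_cols, function(p) as.character(table[[p]][i]),
                     character(1))),
            collapse = "\t")
    }, character(1))
    writeLines(c(hdr, rows), path)
  } else {
    blocks <- vapply(seq_len(nrow(table)), function(i) {
      props <- stats::setNames(
        lapply(prop_cols, function(p) as.character(table[[p]][i])), prop_cols
      )
      write_sdf_block(table$mol[[i]], props)
    }, character(1))
    writeLines(paste0(blocks, collapse = ""), path, sep = "")
  }
  invisible(path)
}

write_sdf_block <- function(mol, extra_props = list()) {
  mol <- kekulize(mol) # V2000 carries explicit Kekule bonds
  na <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  out <- c(
    mol$name, "  qsarkit", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  )
  for (i in seq_len(na)) {
    # MDL atom parity: neighbours in ascending atom number with implicit H
    # last; our tags are normalized with the H slot first, so the tag flips
    # when an implicit H is present (an odd permutation moves it to the end)
    parity <- 0L
    tag <- mol$atoms$chiral[i]
    if (!is.na(tag)) {
      if (mol$atoms$hcount[i] > 0L) tag <- flip_tag(tag)
      parity <- if (tag == "@@") 1L else 2L
    }
    out <- c(out, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0%3d  0  0  0  0  0  0  0  0  0",
      0, 0, 0, mol$atoms$element[i], parity
    ))
  }
  for (i in seq_len(nb)) {
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          mol$bonds$from[i], mol$bonds$to[i],
                          mol$bonds$order[i]))
  }
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg) > 0L) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8L))) {
      out <- c(out, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, mol$atoms$charge[grp]), collapse = "")
      ))
    }
  }
  iso <- which(!is.na(mol$atoms$isotope))
  if (length(iso) > 0L) {
    for (grp in split(iso, ceiling(seq_along(iso) / 8L))) {
      out <- c(out, paste0(
        sprintf("M  ISO%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, mol$atoms$isotope[grp]), collapse = "")
      ))
    }
  }
  out <- c(out, "M  END")
  props <- utils::modifyList(as.list(mol$props), extra_props)
  for (nm in names(props)) {
    out <- c(out, sprintf(">  <%s>", nm), as.character(props[[nm]]), "")
  }
  paste0(paste(out, collapse = "\n"), "\n$$$$\n")
}
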