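`%||%` <- function(a, b) if (is.null(a)) b else a

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

# Sign (+1/-1) of the permutation carrying `from_ord` onto `to_ord`;
# both are vectors of the same ids.
perm_sign <- function(from_ord, to_ord) {
  p <- match(to_ord, from_ord)
  stopifnot(!anyNA(p))
  inv <- 0L
  n <- length(p)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      inv <- inv + sum(p[(i + 1L):n] < p[i])
    }
  }
  if (inv %% 2L == 0L) 1L else -1L
}

flip_tag <- function(tag) if (identical(tag, "@")) "@@" else "@"

#' Parse a SMILES string into a molecular graph
#'
#' Supports the Daylight dialect with the implicit-hydrogen model: the
#' organic subset (B, C, N, O, P, S, F, Cl, Br, I and their aromatic
#' lowercase forms), bracket atoms with isotope, tetrahedral tags (`@`,
#' `@@`), explicit hydrogen counts and formal charges, ring-bond closures
#' (including `%nn`), branches, dot-separated fragments, and the bond
#' symbols `-`, `=`, `#`, `:`, `/`, `\`.
#'
#' Tetrahedral tags are normalized at parse time so that they are expressed
#' relative to the ascending order of neighbour atom indices (an implicit
#' hydrogen sorts first); the writer restores the correct `@`/`@@` for any
#' output ordering, so parity survives re-ordering and canonicalization.
#'
#' @param smiles a single SMILES string.
#' @param name molecule name stored on the result.
#' @return A `mol_graph`.
#' @export
#' @examples
#' mol <- parse_smiles("c1ccccc1O")
#' mol
parse_smiles <- function(smiles, name = "") {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  nch <- length(chars)

  atoms <- list()
  bonds <- list()
  nbord <- list() # written neighbour order per atom (0 = implicit H slot)
  prev <- NA_integer_
  stack <- integer()
  pending <- NULL
  rings <- list() # key -> list(atom, sym, slot)

  fail <- function(msg) stop(sprintf("SMILES parse error in '%s': %s", s, msg),
                             call. = FALSE)

  add_atom <- function(element, charge = 0L, isotope = NA_integer_,
                       hcount = NA_integer_, aromatic = FALSE,
                       chiral = NA_character_) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, charge = as.integer(charge),
      isotope = as.integer(isotope), hcount = as.integer(hcount),
      aromatic = aromatic, chiral = chiral
    )
    nbord[[length(atoms)]] <<- integer()
    length(atoms)
  }

  add_bond <- function(from, to, sym, flip_stereo = FALSE) {
    aromatic <- FALSE
    order <- 1L
    stereo <- NA_character_
    if (is.null(sym)) {
      if (atoms[[from]]$aromatic && atoms[[to]]$aromatic) aromatic <- TRUE
    } else if (sym == "-") {
    } else if (sym == "=") {
      order <- 2L
    } else if (sym == "#") {
      order <- 3L
    } else if (sym == ":") {
      aromatic <- TRUE
    } else if (sym %in% c("/", "\\")) {
      stereo <- if (flip_stereo) setdiff(c("/", "\\"), sym) else sym
    } else {
      fail(paste0("unknown bond symbol '", sym, "'"))
    }
    bonds[[length(bonds) + 1L]] <<- list(
      from = from, to = to, order = order, aromatic = aromatic, stereo = stereo
    )
  }

  read_bracket <- function(i) {
    j <- i
    while (j <= nch && chars[j] != "]") j <- j + 1L
    if (j > nch) fail("unterminated bracket atom")
    body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
    m <- regmatches(body, regexec(
      "^([0-9]*)(\\*|[A-Z][a-z]?|[a-z]{1,2})(@{1,2})?(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
      body
    ))[[1]]
    if (length(m) == 0L) fail(paste0("cannot parse bracket atom [", body, "]"))
    isotope <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
    sym <- m[3]
    aromatic <- sym %in% c(AROMATIC_ORGANIC, "se", "as")
    element <- if (aromatic) {
      paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
    } else sym
    chiral <- if (nzchar(m[4])) m[4] else NA_character_
    hcount <- if (nzchar(m[5])) {
      if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
    } else 0L
    charge <- 0L
    if (nzchar(m[6])) {
      ch <- m[6]
      sign <- if (substr(ch, 1, 1) == "+") 1L else -1L
      digits <- gsub("[+-]", "", ch)
      charge <- if (nzchar(digits)) sign * as.integer(digits) else
        sign * nchar(ch)
    }
    list(j = j, element = element, aromatic = aromatic, chiral = chiral,
         hcount = hcount, charge = charge, isotope = isotope)
  }

  attach_atom <- function(cur, bracket_h_chiral) {
    if (!is.na(prev)) {
      add_bond(prev, cur, pending)
      nbord[[prev]] <<- c(nbord[[prev]], cur)
      nbord[[cur]] <<- c(nbord[[cur]], prev)
    }
    if (bracket_h_chiral) nbord[[cur]] <<- c(nbord[[cur]], 0L)
    pending <<- NULL
    prev <<- cur
  }

  close_ring <- function(key) {
    if (!is.null(rings[[key]])) {
      op <- rings[[key]]
      sym <- pending %||% op$sym
      flip <- !is.null(pending) && is.null(op$sym)
      # stored from = opening atom; a slash typed at the closing end reads
      # cur -> open, so it must be mirrored
      add_bond(op$atom, prev, sym, flip_stereo = flip)
      nbord[[op$atom]][op$slot] <<- prev
      nbord[[prev]] <<- c(nbord[[prev]], op$atom)
      rings[[key]] <<- NULL
    } else {
      nbord[[prev]] <<- c(nbord[[prev]], NA_integer_)
      rings[[key]] <<- list(atom = prev, sym = pending,
                            slot = length(nbord[[prev]]))
    }
    pending <<- NULL
  }

  i <- 1L
  while (i <= nch) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) fail("branch with no preceding atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NULL
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) fail("ring closure with no preceding atom")
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nch) fail("truncated %nn ring closure")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == "[") {
      br <- read_bracket(i)
      cur <- add_atom(br$element, br$charge, br$isotope, br$hcount,
                      br$aromatic, br$chiral)
      attach_atom(cur, !is.na(br$chiral) && br$hcount > 0L)
      i <- br$j + 1L
    } else if (ch == "*") {
      cur <- add_atom("*")
      attach_atom(cur, FALSE)
      i <- i + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < nch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        cur <- add_atom(two)
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        cur <- add_atom(ch)
        i <- i + 1L
      } else {
        fail(paste0("element '", ch, "' must be written in brackets"))
      }
      attach_atom(cur, FALSE)
    } else if (ch %in% AROMATIC_ORGANIC) {
      cur <- add_atom(toupper(ch), aromatic = TRUE)
      attach_atom(cur, FALSE)
      i <- i + 1L
    } else {
      fail(paste0("unexpected character '", ch, "'"))
    }
  }

  if (length(stack) > 0L) fail("unclosed branch")
  if (length(rings) > 0L) fail(
    paste0("unclosed ring bond(s): ", paste(names(rings), collapse = ", "))
  )
  if (length(atoms) == 0L) fail("no atoms")

  atoms_df <- dplyr::bind_rows(lapply(atoms, tibble::as_tibble))
  bonds_df <- if (length(bonds) > 0L) {
    dplyr::bind_rows(lapply(bonds, tibble::as_tibble))
  } else empty_bonds()
  mol <- new_mol_graph(atoms_df, bonds_df, name = name)

  # implicit hydrogens for organic-subset atoms written without brackets
  open_h <- is.na(mol$atoms$hcount)
  if (any(open_h)) {
    mol$atoms$hcount[open_h] <- implicit_hcount(mol)[open_h]
  }

  # normalize tetrahedral tags to ascending-neighbour reference order
  chi <- which(!is.na(mol$atoms$chiral))
  for (a in chi) {
    w <- nbord[[a]]
    if (anyNA(w) || length(w) < 3L) {
      mol$atoms$chiral[a] <- NA_character_
      next
    }
    sgn <- perm_sign(w, sort(w))
    if (sgn < 0L) mol$atoms$chiral[a] <- flip_tag(mol$atoms$chiral[a])
  }
  mol
}

# Default implicit-hydrogen count per atom under the Daylight model:
# the smallest allowed valence not exceeded by the incident bond-order sum.
# Charged or bracket atoms always carry their explicit count.
implicit_hcount <- function(mol) {
  v <- valence_sum(mol)
  el <- mol$atoms$element
  out <- integer(n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) {
    if (!el[i] %in% ORGANIC_SUBSET) {
      out[i] <- 0L
      next
    }
    av <- allowed_valences(el[i], 0L)
    fit <- av[av >= v[i]]
    out[i] <- if (length(fit) > 0L) as.integer(round(fit[1] - v[i])) else 0L
  }
  out
}
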